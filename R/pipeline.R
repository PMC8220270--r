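#' @include alignment.R bivariate.R impute.R simulate.R
NULL

.pooledCentered <- function(mats)
  do.call(rbind, lapply(mats, function(M)
    sweep(as.matrix(M), 2L, colMeans(M), "-")))

#' Run the full allometry analysis from a config
#'
#' Orchestrates the end-to-end analysis for one or both limbs:
#' impute missing cells, log-transform, bivariate allometry (per-species
#' log-log slopes, ANCOVA and MANCOVA species tests, hatchling-adult
#' correlation of relative limb length), ontogenetic multivariate
#' allometry (per-species vectors, pairwise angles against the
#' shared-allometry null, isometry bootstrap of cPC1, allometric space),
#' evolutionary allometry (group-wise phylogenetic PCA and between-group
#' angles, size correlation), and the alignment tests of the ontogenetic
#' axis against each group's evolutionary axis. Results are returned and
#' written as CSV tables, each stamped with a fingerprint of the config;
#' a plain-text run log records the seed, bootstrap size, element lists
#' and exclusions.
#'
#' @param config a YAML file path or an equivalent named list with
#'   entries: `onto_table`, `adult_table`, `tree`, `groups` (file paths);
#'   `limbs` (subset of `"forelimb"`, `"hindlimb"`); `exclude_onto`
#'   (species dropped from the ontogenetic side of the alignment test);
#'   `B`; `seed`; `mode` (`"ppca"` or `"pca"`); optional `impute` list
#'   (`onto_scope`, `adult_scope`, `tol`, `max_iter`); `out_dir`.
#' @param out_dir overrides `config$out_dir` when given.
#' @return invisibly, a nested list of results by limb.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfgHash <- .configHash(yaml::as.yaml(config))
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  limbs <- config$limbs %||% c("forelimb", "hindlimb")
  B <- as.integer(config$B %||% 1000L)
  if (B < 100L) stop("config B must be at least 100")
  seed <- as.integer(config$seed %||% 1L)
  mode <- config$mode %||% "ppca"
  excl <- as.character(config$exclude_onto %||% character())
  imp <- config$impute %||% list()
  tol <- imp$tol %||% 1e-6
  max_iter <- as.integer(imp$max_iter %||% 500L)
  tree <- readTreeFile(config$tree)
  groups <- readGroupMap(config$groups)
  emit <- function(df, name) {
    df$config_hash <- cfgHash
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  logLines <- c(sprintf("alloaxis %s | %s",
                        as.character(utils::packageVersion("alloaxis")),
                        format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                sprintf("config_hash: %s", cfgHash),
                sprintf("seed: %d | B: %d | mode: %s", seed, B, mode),
                sprintf("limbs: %s", paste(limbs, collapse = ", ")),
                sprintf("excluded ontogenetic species: %s",
                        if (length(excl)) paste(excl, collapse = ", ")
                        else "none"))
  results <- list()
  for (limb in limbs) {
    elements <- limbElements(limb)
    logLines <- c(logLines, sprintf("%s elements: %s", limb,
                                    paste(elements, collapse = ", ")))
    ## --- data: read, impute, log ------------------------------------
    onto <- readMeasurements(config$onto_table, elements = elements)
    onto <- imputeMissing(onto, scope = imp$onto_scope %||% "per_species",
                          tol = tol, max_iter = max_iter)
    adult <- readMeasurements(config$adult_table, elements = elements)
    adult <- imputeMissing(adult, scope = imp$adult_scope %||% "global",
                           tol = tol, max_iter = max_iter)
    rllOnto <- relativeLimbLength(onto)
    rllAdult <- relativeLimbLength(adult)
    ontoLog <- logTransform(onto)
    adultLog <- logTransform(adult)
    adultMeans <- speciesMeans(adultLog)
    ## --- bivariate ---------------------------------------------------
    totalLimb <- log(rowSums(measurementMatrix(onto)))
    fits <- fitLogLog(totalLimb, sizeProxy(ontoLog),
                      species = speciesOf(onto))
    anc <- ancovaSpecies(totalLimb, sizeProxy(ontoLog), speciesOf(onto))
    man <- tryCatch(
      mancovaSpecies(measurementMatrix(ontoLog), sizeProxy(ontoLog),
                     speciesOf(onto)),
      error = function(e) {
        warning("MANCOVA skipped: ", conditionMessage(e)); NULL
      })
    emit(fits, sprintf("bivariate_slopes_%s.csv", limb))
    emit(rbind(cbind(test = "ANCOVA", anc[c("effect", "F", "df1", "df2",
                                            "p_value")]),
               if (!is.null(man))
                 cbind(test = "MANCOVA", man[c("effect", "F", "df1",
                                               "df2", "p_value")])),
         sprintf("species_tests_%s.csv", limb))
    ## hatchling vs adult relative limb length, species means
    hrows <- lifeStage(onto) == "hatchling"
    stageCor <- NULL
    hat <- onto[, hrows]
    shared <- intersect(unique(speciesOf(hat)), unique(speciesOf(adult)))
    if (length(shared) >= 3L) {
      h <- tapply(rllOnto[hrows], speciesOf(hat), mean)[shared]
      a <- tapply(rllAdult, speciesOf(adult), mean)[shared]
      stageCor <- correlateLifeStages(h, a)
      emit(cbind(comparison = sprintf("relative_%s_length", limb),
                 stageCor),
           sprintf("stage_correlation_%s.csv", limb))
    }
    ## --- ontogenetic multivariate ------------------------------------
    vecs <- speciesVectors(ontoLog)
    angles <- sharedAllometryNull(ontoLog, B = B, seed = seed)
    cpc1 <- commonAllometricVector(ontoLog)
    iso <- isometryBootstrap(.pooledCentered(.speciesMatrices(ontoLog)),
                             B = B, seed = seed + 1L)
    space <- allometricSpace(vecs)
    emit(data.frame(species = names(vecs),
                    t(vapply(vecs, vectorCoefficients,
                             numeric(length(elements)))),
                    variance_fraction = vapply(vecs, varianceFraction, 0)),
         sprintf("vectors_%s.csv", limb))
    emit(as.data.frame(angles@pairs),
         sprintf("angles_%s.csv", limb))
    emit(as.data.frame(iso@table), sprintf("isometry_%s.csv", limb))
    emit(data.frame(species = rownames(space@scores),
                    space@scores[, 1:2, drop = FALSE]),
         sprintf("allometric_space_%s.csv", limb))
    ## --- evolutionary ------------------------------------------------
    checkGroupCoverage(adultMeans, groups, excluded = excl)
    gev <- groupEvolutionaryVectors(adultMeans, tree, groups, mode = mode,
                                    B = B, seed = seed + 2L)
    sizes <- stats::setNames(sizeProxy(adultMeans), speciesOf(adultMeans))
    sizeCors <- do.call(rbind, lapply(names(gev$ppca), function(g) {
      sc <- correlateWithSize(gev$ppca[[g]],
                              sizes[rownames(gev$ppca[[g]]@scores)])
      cbind(group = g, sc)
    }))
    emit(do.call(rbind, lapply(names(gev$vectors), function(g) {
      v <- gev$vectors[[g]]
      data.frame(group = g, t(vectorCoefficients(v)),
                 variance_fraction = varianceFraction(v))
    })), sprintf("ppca_vectors_%s.csv", limb))
    if (!is.null(gev$angles))
      emit(as.data.frame(gev$angles@pairs),
           sprintf("group_angles_%s.csv", limb))
    emit(sizeCors, sprintf("size_correlation_%s.csv", limb))
    ## --- alignment ---------------------------------------------------
    sp_means <- speciesOf(adultMeans)
    glev <- intersect(names(gev$vectors), unique(groups[sp_means]))
    aligns <- lapply(glev, function(g) {
      gsp <- sp_means[groups[sp_means] == g]
      alignedNull(ontoLog,
                  adultMeans[, speciesOf(adultMeans) %in% gsp],
                  tree, exclude = excl, mode = mode, B = B,
                  seed = seed + 3L, label = paste0("ont-", g))
    })
    names(aligns) <- glev
    hva <- NULL
    if (length(shared) >= length(elements) + 1L) {
      hatMeans <- speciesMeans(logTransform(
        imputeMissing(hat[, speciesOf(hat) %in% shared])))
      hva <- hatchlingVsAdult(
        hatMeans, adultMeans[, speciesOf(adultMeans) %in% shared],
        tree, mode = mode, B = B, seed = seed + 4L,
        label = "hatchling-adult")
    }
    alignRows <- do.call(rbind, lapply(c(aligns, list(hva)), function(a) {
      if (is.null(a)) return(NULL)
      data.frame(comparison = a@label, theta_deg = a@thetaObs,
                 null_q95_deg = a@ci95Upper, aligned = a@aligned,
                 B = a@B, seed = a@seed)
    }))
    emit(alignRows, sprintf("alignment_%s.csv", limb))
    results[[limb]] <- list(
      bivariate = list(fits = fits, ancova = anc, mancova = man,
                       stage_correlation = stageCor),
      vectors = vecs, cpc1 = cpc1, angles = angles, isometry = iso,
      space = space, groups = gev, size_correlations = sizeCors,
      alignment = aligns, hatchling_vs_adult = hva)
  }
  writeLines(logLines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
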