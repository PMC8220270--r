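# Fixtures are built in code at test time; nothing binary is stored.

fore6 <- alloaxis::limbElements("forelimb")
hind7 <- alloaxis::limbElements("hindlimb")

# A tiny 3-specimen forelimb table as a data.frame ready for write/read.
smallTableDf <- function(missing_humerus_row = NULL) {
  set.seed(42)
  M <- matrix(round(runif(18, 1, 5), 3), 3, 6,
              dimnames = list(NULL, fore6))
  df <- data.frame(specimen_id = c("e1", "e2", "e3"),
                   species = c("spA", "spA", "spB"),
                   life_stage = "embryo",
                   size_proxy = c(10.5, 12.25, 9.75))
  df <- cbind(df, as.data.frame(M))
  if (!is.null(missing_humerus_row))
    df$humerus[missing_humerus_row] <- NA
  df
}

writeFixtureCsv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Noiseless rank-1 table on the linear scale: log(row r) = a + c_r * v.
rank1Table <- function(n = 10, v = c(2, 1, 3, 1, 2, 1) / sqrt(20),
                       elements = fore6, species = "spA") {
  scores <- seq(0, 3, length.out = n)
  L <- exp(outer(scores, v) +
             matrix(log(2), n, length(v)))
  colnames(L) <- as.character(elements)
  alloaxis::LimbMeasurements(
    L, specimen_id = sprintf("%s_%02d", species, seq_len(n)),
    species = species, life_stage = "embryo",
    size_proxy = exp(scores / 2 + 1))
}

# Brute-force first eigenvector of the covariance of X (independent of the
# package's SVD path): covariance by explicit loops, then eigen().
oraclePC1 <- function(X) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  S <- matrix(0, p, p)
  for (i in seq_len(n)) {
    d <- X[i, ] - ctr
    S <- S + outer(d, d)
  }
  S <- S / (n - 1)
  v <- eigen(S, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v
}

# Brute-force patristic distance between two tips by summing edge lengths
# along root-to-tip paths (independent of ape's cophenetic machinery).
oraclePatristic <- function(tree, a, b) {
  pathToRoot <- function(tip) {
    node <- which(tree$tip.label == tip)
    edges <- integer()
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  ea <- pathToRoot(a); eb <- pathToRoot(b)
  shared <- intersect(ea, eb)
  sum(tree$edge.length[setdiff(ea, shared)]) +
    sum(tree$edge.length[setdiff(eb, shared)])
}

# Independent phylogenetic-PCA oracle from the explicit matrix formulas.
oraclePPCA <- function(X, C) {
  n <- nrow(X)
  one <- matrix(1, n, 1)
  Ci <- solve(C)
  a <- drop(solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% X)
  Xc <- X - one %*% t(a)
  R <- t(Xc) %*% Ci %*% Xc / (n - 1)
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  list(mean = a, vectors = V, values = eg$values, scores = Xc %*% V)
}

# Write a complete synthetic study (ontogenetic table with both limbs,
# adult specimens, tree, group map, YAML config) into `dir` and return the
# config path. Tree tips sp01..spNN; ontogenetic species are the first
# n_species tips.
makePipelineFixture <- function(dir, n_species = 9, n_per = 15,
                                n_tips = 36, B = 150, seed = 5,
                                mode = "ppca", star_tree = FALSE,
                                missing_fraction = 0.03) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v6 <- c(1.25, 1.25, 1, 1, 1, 1); v6 <- v6 / sqrt(sum(v6^2))
  v7 <- c(1.25, 1.25, 1, 1, 1, 1, 1); v7 <- v7 / sqrt(sum(v7^2))
  of <- alloaxis::simulateOntogeny(n_species, n_per, elements = fore6,
                                   common_vector = v6,
                                   missing_fraction = missing_fraction,
                                   seed = seed)
  oh <- alloaxis::simulateOntogeny(n_species, n_per, elements = hind7,
                                   common_vector = v7,
                                   missing_fraction = missing_fraction,
                                   seed = seed + 1)
  cd <- SummarizedExperiment::colData(of)
  onto <- cbind(data.frame(specimen_id = cd$specimen_id,
                           species = cd$species,
                           life_stage = cd$life_stage,
                           size_proxy = cd$size_proxy,
                           stage = cd$stage),
                as.data.frame(alloaxis::measurementMatrix(of)),
                as.data.frame(alloaxis::measurementMatrix(oh)))
  write.csv(onto, file.path(dir, "onto.csv"), row.names = FALSE, na = "")
  tree <- if (star_tree) {
    ape::read.tree(text = paste0(
      "(", paste(sprintf("sp%02d:1", seq_len(n_tips)), collapse = ","),
      "):0;"))
  } else alloaxis::simulateTree(n_tips, seed = seed + 2)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  ef <- alloaxis::simulateEvolution(tree, rep(log(10), 6),
                                    alloaxis::rank1Covariance(v6, 0.4, 0.95),
                                    elements = fore6, seed = seed + 3)
  eh <- alloaxis::simulateEvolution(tree, rep(log(12), 7),
                                    alloaxis::rank1Covariance(v7, 0.4, 0.95),
                                    elements = hind7, seed = seed + 4)
  MF <- alloaxis::measurementMatrix(ef)
  MH <- alloaxis::measurementMatrix(eh)
  sz <- alloaxis::sizeProxy(ef)
  set.seed(seed + 5)
  rows <- lapply(seq_len(n_tips), function(i) {
    k <- 2  # two adult specimens per species
    data.frame(specimen_id = sprintf("ad_%s_%d", rownames(MF)[i], 1:k),
               species = rownames(MF)[i], life_stage = "adult",
               size_proxy = exp(sz[i] + rnorm(k, sd = 0.02)),
               exp(matrix(MF[i, ], k, 6, byrow = TRUE) +
                     matrix(rnorm(6 * k, sd = 0.02), k, 6,
                            dimnames = list(NULL, fore6))),
               exp(matrix(MH[i, ], k, 7, byrow = TRUE) +
                     matrix(rnorm(7 * k, sd = 0.02), k, 7,
                            dimnames = list(NULL, hind7))))
  })
  adult <- do.call(rbind, rows)
  colnames(adult)[5:17] <- c(fore6, hind7)
  write.csv(adult, file.path(dir, "adult.csv"), row.names = FALSE, na = "")
  ngrp <- ceiling(n_tips / 3)
  groups <- data.frame(species = sprintf("sp%02d", seq_len(n_tips)),
                       group = rep(c("Ant", "MLpri", "MLsec"),
                                   length.out = n_tips))
  # keep all ontogenetic species in one (Antillean) group
  groups$group[seq_len(n_species)] <- "Ant"
  groups$group[seq.int(n_species + 1, n_tips)] <-
    rep(c("Ant", "MLpri", "MLsec"),
        length.out = n_tips - n_species)
  write.csv(groups, file.path(dir, "groups.csv"), row.names = FALSE)
  cfg <- list(onto_table = file.path(dir, "onto.csv"),
              adult_table = file.path(dir, "adult.csv"),
              tree = file.path(dir, "tree.nwk"),
              groups = file.path(dir, "groups.csv"),
              limbs = list("forelimb", "hindlimb"),
              exclude_onto = list(),
              B = B, seed = seed, mode = mode,
              impute = list(onto_scope = "per_species",
                            adult_scope = "global"),
              out_dir = file.path(dir, "out"))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  cfgPath
}

# Full study-scale synthetic fixture: 15 ontogenetic species (374 rows
# after dropping one specimen), a 267-species tree with major groups of
# 121 Antillean, 29 Primary-Mainland and 107 Secondary-Mainland species
# (plus 10 outside the groups), and 693 adult specimens collapsing to 267
# species means. One ontogenetic species is mapped outside the groups and
# excluded from the alignment comparisons.
makeStudyScaleFixture <- function(dir, B = 1000, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v6 <- c(1.25, 1.25, 1, 1, 1, 1); v6 <- v6 / sqrt(sum(v6^2))
  v7 <- c(1.25, 1.25, 1, 1, 1, 1, 1); v7 <- v7 / sqrt(sum(v7^2))
  n_tips <- 267
  tree <- alloaxis::simulateTree(n_tips, seed = seed + 2)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  # one latent body-size signal on the tree drives both limbs: the
  # forelimb evolves rank-1-dominant along v6, the hindlimb reuses the
  # same axis scores plus Brownian noise in the complement of v7, and the
  # size proxy tracks the shared signal
  ef <- alloaxis::simulateEvolution(tree, rep(log(10), 6),
                                    alloaxis::rank1Covariance(v6, 1.2, 0.94),
                                    elements = fore6, seed = seed + 3)
  MF <- alloaxis::measurementMatrix(ef)     # log scale
  tscore <- drop((MF - log(10)) %*% v6)
  P7 <- diag(7) - v7 %o% v7
  ehn <- alloaxis::simulateEvolution(tree, rep(0, 7), 0.072 * P7 / 6,
                                     elements = hind7, seed = seed + 4)
  MH <- log(12) + outer(tscore, v7) + alloaxis::measurementMatrix(ehn)
  dimnames(MH) <- list(rownames(MF), hind7)
  sz <- alloaxis::sizeProxy(ef)
  # persistent species differences in limb length relative to body size:
  # a uniform log offset of all limb elements (both limbs, all stages)
  # that the body-size proxies do not share
  set.seed(seed + 7)
  rel <- rnorm(n_tips, sd = 0.15)
  MF <- MF + rel; MH <- MH + rel
  # the 15 ontogenetic species are the first 15 tips; their anlage
  # intercepts shrink the adult means down the shared axis so hatchling
  # proportions anticipate adult proportions, as in the emulated design
  icf <- MF[1:15, ] - matrix(5 * v6, 15, 6, byrow = TRUE) - 1.1
  ich <- MH[1:15, ] - matrix(5 * v7, 15, 7, byrow = TRUE) - 1.1
  set.seed(seed + 6)
  icf <- icf + matrix(rnorm(90, sd = 0.05), 15, 6)
  ich <- ich + matrix(rnorm(105, sd = 0.05), 15, 7)
  of <- alloaxis::simulateOntogeny(15, 25, elements = fore6,
                                   common_vector = v6,
                                   anlage_intercepts = icf, seed = seed)
  oh <- alloaxis::simulateOntogeny(15, 25, elements = hind7,
                                   common_vector = v7,
                                   anlage_intercepts = ich,
                                   seed = seed + 1)
  cd <- SummarizedExperiment::colData(of)
  onto <- cbind(data.frame(specimen_id = cd$specimen_id,
                           species = sprintf("sp%03d",
                                             as.integer(sub("sp", "",
                                                            cd$species))),
                           life_stage = cd$life_stage,
                           size_proxy = cd$size_proxy,
                           stage = cd$stage),
                as.data.frame(alloaxis::measurementMatrix(of)),
                as.data.frame(alloaxis::measurementMatrix(oh)))
  onto <- onto[-nrow(onto), ]          # 374 specimens
  write.csv(onto, file.path(dir, "onto.csv"), row.names = FALSE, na = "")
  # 159 species x 3 + 108 species x 2 = 693 adult specimens
  kper <- rep(c(3L, 2L), c(159L, 108L))
  set.seed(seed + 5)
  rows <- lapply(seq_len(n_tips), function(i) {
    k <- kper[i]
    data.frame(specimen_id = sprintf("ad_%s_%d", rownames(MF)[i],
                                     seq_len(k)),
               species = rownames(MF)[i], life_stage = "adult",
               size_proxy = exp(sz[i] + rnorm(k, sd = 0.02)),
               exp(matrix(MF[i, ], k, 6, byrow = TRUE) +
                     matrix(rnorm(6 * k, sd = 0.02), k, 6,
                            dimnames = list(NULL, fore6))),
               exp(matrix(MH[i, ], k, 7, byrow = TRUE) +
                     matrix(rnorm(7 * k, sd = 0.02), k, 7,
                            dimnames = list(NULL, hind7))))
  })
  adult <- do.call(rbind, rows)
  colnames(adult)[5:17] <- c(fore6, hind7)
  write.csv(adult, file.path(dir, "adult.csv"), row.names = FALSE, na = "")
  grp <- character(n_tips)
  grp[1:14] <- "Ant"; grp[15] <- "other"        # sp015 sits outside
  grp[16:122] <- "Ant"                          # 121 Antillean in total
  grp[123:151] <- "MLpri"                       # 29
  grp[152:258] <- "MLsec"                       # 107
  grp[259:267] <- "other"
  groups <- data.frame(species = sprintf("sp%03d", seq_len(n_tips)),
                       group = grp)
  write.csv(groups, file.path(dir, "groups.csv"), row.names = FALSE)
  cfg <- list(onto_table = file.path(dir, "onto.csv"),
              adult_table = file.path(dir, "adult.csv"),
              tree = file.path(dir, "tree.nwk"),
              groups = file.path(dir, "groups.csv"),
              limbs = list("forelimb", "hindlimb"),
              exclude_onto = list("sp015"),
              B = B, seed = seed, mode = "ppca",
              impute = list(onto_scope = "per_species",
                            adult_scope = "global"),
              out_dir = file.path(dir, "out"))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  cfgPath
}

# Simulated ontogeny + matching evolutionary means sharing one true axis,
# for alignment tests. Returns list(ontoLog, means, tree, v).
alignedWorld <- function(n_species = 14, n_per = 25, n_tips = 60,
                         offset_deg = 0, evo_noise = 0.02, seed = 1) {
  v <- c(1.25, 1.25, 1, 1, 1, 1)
  v <- v / sqrt(sum(v^2))
  onto <- alloaxis::simulateOntogeny(
    n_species = n_species, n_per_species = n_per,
    common_vector = v, perturbation_deg = 0, residual_sd = 0.05,
    missing_fraction = 0, seed = seed)
  ontoLog <- alloaxis::logTransform(onto)
  tree <- alloaxis::simulateTree(n_tips, seed = seed + 1)
  vEvo <- if (offset_deg == 0) v else {
    set.seed(seed + 2)
    alloaxis:::.tiltVector(v, offset_deg)
  }
  means <- alloaxis::simulateEvolution(
    tree, root_state = rep(log(10), 6),
    bm_covariance = alloaxis::rank1Covariance(vEvo, 0.4,
                                              1 - evo_noise),
    seed = seed + 3)
  list(ontoLog = ontoLog, means = means, tree = tree, v = v, vEvo = vEvo)
}
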