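#' @include measurements.R
NULL

#' Relative limb length
#'
#' The sum of a limb's bone lengths divided by the body-size proxy (spine
#' length for embryos and hatchlings, pelvic-girdle centroid size for
#' adults). Summation happens on the linear scale before division, so the
#' ratio is dimensionless and invariant to rescaling all lengths jointly.
#'
#' @param x a complete, linear-scale [LimbMeasurements] object.
#' @param elements the limb's element columns (default: all elements in
#'   `x`).
#' @return numeric vector of per-specimen ratios, named by specimen id.
#' @export
relativeLimbLength <- function(x, elements = rownames(x)) {
  if (isLogScale(x))
    stop("relative limb length is defined on the linear scale")
  M <- measurementMatrix(x)[, as.character(elements), drop = FALSE]
  if (anyNA(M)) stop("table has missing cells; impute first")
  sz <- sizeProxy(x)
  if (any(sz == 0)) stop("size proxy contains zeros")
  stats::setNames(rowSums(M) / sz,
                  SummarizedExperiment::colData(x)$specimen_id)
}

#' Ordinary least-squares log-log allometry fit
#'
#' Fits `y = intercept + slope * x` by OLS and tests the slope against 1
#' (isometry of the bivariate relationship): `t = (slope - 1) / se` with
#' `n - 2` degrees of freedom. Slopes above 1 mean the response grows
#' proportionally faster than the size variable.
#'
#' @param y,x numeric vectors on the log scale.
#' @param species optional grouping; when given, one fit per species.
#' @return a data.frame with columns `species` (when grouped), `n`, `slope`,
#'   `intercept`, `slope_se`, `ci_lower`, `ci_upper`, `t_vs_1`, `p_vs_1`.
#' @export
fitLogLog <- function(y, x, species = NULL) {
  stopifnot(length(y) == length(x))
  if (is.null(species)) {
    res <- .ols1(y, x)
    return(as.data.frame(res))
  }
  sp <- as.character(species)
  out <- do.call(rbind, lapply(unique(sp), function(s) {
    r <- .ols1(y[sp == s], x[sp == s])
    cbind(data.frame(species = s, stringsAsFactors = FALSE),
          as.data.frame(r))
  }))
  rownames(out) <- NULL
  out
}

.ols1 <- function(y, x) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations per fit")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[2L]
  tcrit <- stats::qt(0.975, n - 2L)
  tv1 <- (cf[[2L]] - 1) / se
  list(n = n, slope = cf[[2L]], intercept = cf[[1L]], slope_se = se,
       ci_lower = cf[[2L]] - tcrit * se, ci_upper = cf[[2L]] + tcrit * se,
       t_vs_1 = tv1, p_vs_1 = 2 * stats::pt(abs(tv1), n - 2L,
                                            lower.tail = FALSE))
}

#' ANCOVA for species differences in bivariate allometry
#'
#' Nested-model F tests on a log response against a log size covariate:
#' the species main effect compares the common-slope model
#' `y ~ x` with `y ~ x + species` (intercept differences), and the
#' interaction compares `y ~ x + species` with `y ~ x * species` (slope
#' differences).
#'
#' @param y log response (e.g. log total limb length).
#' @param x log size covariate.
#' @param species species factor (2 or more levels, each with 3 or more
#'   observations).
#' @return data.frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p_value`.
#' @export
ancovaSpecies <- function(y, x, species) {
  species <- factor(species)
  if (nlevels(species) < 2L)
    stop("ANCOVA needs at least two species")
  if (any(table(species) < 3L))
    stop("every species needs at least 3 observations")
  m0 <- stats::lm(y ~ x)
  m1 <- stats::lm(y ~ x + species)
  m2 <- stats::lm(y ~ x * species)
  a1 <- stats::anova(m0, m1)
  a2 <- stats::anova(m1, m2)
  data.frame(
    effect = c("species", "species:size"),
    F = c(a1$F[2L], a2$F[2L]),
    df1 = c(a1$Df[2L], a2$Df[2L]),
    df2 = c(a1$Res.Df[2L], a2$Res.Df[2L]),
    p_value = c(a1$`Pr(>F)`[2L], a2$`Pr(>F)`[2L]),
    stringsAsFactors = FALSE)
}

#' MANCOVA for species differences across individual limb elements
#'
#' Multivariate linear model of all log element lengths on log size, species
#' and their interaction, summarized by Pillai's trace with its approximate
#' F (the most robust of the classical multivariate statistics). Effects are
#' assessed sequentially (size, then species, then the interaction).
#'
#' @param Y matrix of log element lengths (specimens by elements).
#' @param x log size covariate.
#' @param species species factor; every species needs more observations
#'   than there are elements.
#' @return data.frame with rows `species` and `species:size`: `effect`,
#'   `Pillai`, `F`, `df1`, `df2`, `p_value`.
#' @export
mancovaSpecies <- function(Y, x, species) {
  Y <- as.matrix(Y)
  species <- factor(species)
  if (nlevels(species) < 2L)
    stop("MANCOVA needs at least two species")
  if (any(table(species) <= ncol(Y)))
    stop("every species needs more observations than elements (p = ",
         ncol(Y), ")")
  fit <- stats::manova(Y ~ x * species)
  sm <- summary(fit, test = "Pillai")$stats
  rows <- c("species", "x:species")
  if (!all(rows %in% rownames(sm)))
    stop("rank-deficient design; could not estimate all effects")
  data.frame(
    effect = c("species", "species:size"),
    Pillai = sm[rows, "Pillai"],
    F = sm[rows, "approx F"],
    df1 = sm[rows, "num Df"],
    df2 = sm[rows, "den Df"],
    p_value = sm[rows, "Pr(>F)"],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation of species traits between two life stages
#'
#' Pearson product-moment correlation between species-level values at two
#' life stages (e.g. relative hindlimb length at hatching vs adulthood),
#' with the usual two-sided t-test p-value. Both vectors must be named by
#' species and cover the same species set.
#'
#' @param stage1,stage2 named numeric vectors of per-species values.
#' @return data.frame with `r`, `p_value`, `n`.
#' @export
correlateLifeStages <- function(stage1, stage2) {
  if (is.null(names(stage1)) || is.null(names(stage2)))
    stop("both vectors must be named by species")
  if (!setequal(names(stage1), names(stage2)))
    stop("species sets differ: ",
         paste(union(setdiff(names(stage1), names(stage2)),
                     setdiff(names(stage2), names(stage1))),
               collapse = ", "))
  stage2 <- stage2[names(stage1)]
  if (length(stage1) < 3L) stop("need at least 3 species")
  ct <- stats::cor.test(stage1, stage2, method = "pearson")
  data.frame(r = unname(ct$estimate), p_value = ct$p.value,
             n = length(stage1))
}
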