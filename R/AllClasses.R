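#' @include utils-linalg.R
NULL

## Default limb element configurations. Element order is fixed
## proximo-distally: long bones, metapodial, then the phalanges of the
## longest digit.
.FORELIMB <- c("humerus", "ulna", "metacarpal",
               "phalanx_f1", "phalanx_f2", "phalanx_f3")
.HINDLIMB <- c("femur", "tibia", "metatarsus",
               "phalanx_h1", "phalanx_h2", "phalanx_h3", "phalanx_h4")
.LIFE_STAGES <- c("embryo", "hatchling", "adult")
.GROUP_LEVELS <- c("Ant", "MLpri", "MLsec", "other")

#' Limb element configuration
#'
#' Returns the ordered element names measured for one limb: six bones for the
#' forelimb (humerus, ulna, metacarpal and three phalanges of the longest
#' digit) and seven for the hindlimb (femur, tibia, metatarsus and four
#' phalanges). The count `p` of elements is the dimensionality of every
#' allometric vector for that limb, and the multivariate isometry expectation
#' for each coefficient is `p^-0.5`.
#'
#' @param limb `"forelimb"` or `"hindlimb"`.
#' @return character vector of element names, with attribute `limb`.
#' @export
#' @examples
#' limbElements("forelimb")
#' length(limbElements("hindlimb"))
limbElements <- function(limb = c("forelimb", "hindlimb")) {
  limb <- match.arg(limb)
  out <- if (limb == "forelimb") .FORELIMB else .HINDLIMB
  structure(out, limb = limb)
}

#' @describeIn limbElements number of elements measured for one limb.
#' @export
limbElementCount <- function(limb = c("forelimb", "hindlimb"))
  length(limbElements(limb))

#' Container for limb-bone measurement tables
#'
#' `LimbMeasurements` extends
#' [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `"lengths"`, holding the element-by-specimen matrix of bone lengths
#' (millimetres on the linear scale, log-millimetres after
#' [logTransform()]). Per-specimen metadata lives in `colData`:
#' `specimen_id`, `species`, `life_stage` (embryo / hatchling / adult),
#' `size_proxy` (spine length for embryos and hatchlings, pelvic-girdle
#' centroid size for adults) and optionally `stage` (staging-table number
#' for embryos). `metadata(x)$log_scale` records the scale.
#'
#' @slot . inherits all slots from `SummarizedExperiment`.
#' @export
setClass("LimbMeasurements", contains = "SummarizedExperiment")

setValidity("LimbMeasurements", function(object) {
  msgs <- character()
  if (!"lengths" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'lengths' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("specimen_id", "species", "life_stage", "size_proxy")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(cd$specimen_id))
      msgs <- c(msgs, "specimen_id values must be unique")
    if (!all(cd$life_stage %in% .LIFE_STAGES))
      msgs <- c(msgs, paste0("life_stage must be one of: ",
                             paste(.LIFE_STAGES, collapse = ", ")))
    A <- SummarizedExperiment::assay(object, "lengths")
    ls <- isTRUE(S4Vectors::metadata(object)$log_scale)
    if (!ls) {
      bad <- which(!is.na(A) & A <= 0)
      if (length(bad))
        msgs <- c(msgs, paste0(length(bad),
                               " non-positive length(s) on the linear scale"))
      if (any(!is.na(cd$size_proxy) & cd$size_proxy <= 0))
        msgs <- c(msgs, "size_proxy must be positive on the linear scale")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Allometric vector (unit loading vector over limb elements)
#'
#' The first principal component of log bone lengths for a group of
#' observations, normalized to unit Euclidean norm and oriented so that the
#' coefficient sum is positive. Its coefficients describe the relative growth
#' rate of each element along the major axis of covariation; under
#' multivariate isometry every coefficient equals `p^-0.5`.
#'
#' @slot coefficients named unit numeric vector, one entry per element.
#' @slot source one of `"species PC1"`, `"common cPC1"`,
#'   `"evolutionary pPC1"`, `"evolutionary PC1"`.
#' @slot varianceFraction fraction of total variance on this axis.
#' @slot nUsed number of observations (specimens or species) used.
#' @slot label free-text label (species or group name).
#' @export
setClass("AllometricVector",
  representation(coefficients = "numeric", source = "character",
                 varianceFraction = "numeric", nUsed = "integer",
                 label = "character"))

setValidity("AllometricVector", function(object) {
  v <- object@coefficients
  msgs <- character()
  if (abs(sqrt(sum(v^2)) - 1) > 1e-12)
    msgs <- c(msgs, "coefficients must have unit Euclidean norm")
  if (sum(v) < 0)
    msgs <- c(msgs, "coefficients must be oriented to positive sum")
  if (is.null(names(v)))
    msgs <- c(msgs, "coefficients must be named by element")
  if (length(object@varianceFraction) == 1 &&
      (object@varianceFraction < 0 || object@varianceFraction > 1))
    msgs <- c(msgs, "varianceFraction must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Pairwise angle test results
#'
#' One row per unordered pair of allometric vectors: the observed angle
#' \eqn{\Theta} (degrees), the 95% quantile of its bootstrap null
#' distribution under a shared-allometry construction, and whether the
#' observed angle exceeds it.
#'
#' @slot pairs `DataFrame` with columns `label1`, `label2`, `theta_deg`,
#'   `null_q95_deg`, `exceeds_null`.
#' @slot angles symmetric numeric matrix of observed angles (zero diagonal).
#' @slot meanAngle mean over the unordered pairs, degrees.
#' @slot B bootstrap iteration count (0 when no null was computed).
#' @slot seed RNG seed used for the null.
#' @export
setClass("AngleTestSet",
  representation(pairs = "DFrame", angles = "matrix", meanAngle = "numeric",
                 B = "integer", seed = "integer"))

setValidity("AngleTestSet", function(object) {
  msgs <- character()
  A <- object@angles
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8)
    msgs <- c(msgs, "angle matrix must be symmetric")
  if (any(diag(A) != 0))
    msgs <- c(msgs, "angle matrix must have a zero diagonal")
  if (object@B > 0 && object@B < 100)
    msgs <- c(msgs, "bootstrap count B must be at least 100")
  pr <- object@pairs
  if (all(c("theta_deg", "null_q95_deg", "exceeds_null") %in% colnames(pr))) {
    ok <- is.na(pr$null_q95_deg) |
      (pr$exceeds_null == (pr$theta_deg > pr$null_q95_deg))
    if (!all(ok))
      msgs <- c(msgs, "exceeds_null must equal theta_deg > null_q95_deg")
  }
  if (length(msgs)) msgs else TRUE
})

#' Bootstrap test of multivariate isometry
#'
#' Per-element percentile bootstrap confidence intervals for the allometric
#' vector coefficients, classified against the isometry expectation
#' `p^-0.5`: `"positive"` allometry when the interval lies entirely above it,
#' `"negative"` when entirely below, `"isometry"` otherwise.
#'
#' @slot table `DataFrame` with columns `element`, `coefficient`,
#'   `ci_lower`, `ci_upper`, `classification`.
#' @slot isometryValue the value `p^-0.5`.
#' @slot B,seed bootstrap iteration count and RNG seed.
#' @export
setClass("IsometryTest",
  representation(table = "DFrame", isometryValue = "numeric",
                 B = "integer", seed = "integer"))

setValidity("IsometryTest", function(object) {
  tb <- object@table
  iso <- object@isometryValue
  msgs <- character()
  if (object@B < 100)
    msgs <- c(msgs, "bootstrap count B must be at least 100")
  expected <- ifelse(tb$ci_lower > iso, "positive",
                     ifelse(tb$ci_upper < iso, "negative", "isometry"))
  if (!all(tb$classification == expected))
    msgs <- c(msgs, "classification inconsistent with interval vs p^-0.5")
  if (length(msgs)) msgs else TRUE
})

#' Allometric space ordination
#'
#' A second-order PCA in which each observation is one species' allometric
#' vector; species close together share a pattern of relative bone growth.
#'
#' @slot scores species-by-axis score matrix (centered).
#' @slot loadings element-by-axis loading matrix.
#' @slot varianceFraction per-axis fraction of variance, nonincreasing.
#' @export
setClass("AllometricSpace",
  representation(scores = "matrix", loadings = "matrix",
                 varianceFraction = "numeric"))

setValidity("AllometricSpace", function(object) {
  msgs <- character()
  if (max(abs(colMeans(object@scores))) > 1e-8)
    msgs <- c(msgs, "scores must be column-centered")
  vf <- object@varianceFraction
  if (any(diff(vf) > 1e-8))
    msgs <- c(msgs, "variance fractions must be nonincreasing")
  if (length(msgs)) msgs else TRUE
})

#' Phylogenetic (or standard) PCA of species means
#'
#' Eigen-decomposition of the evolutionary trait covariance estimated from
#' species means. In `"ppca"` mode the mean is the generalized-least-squares
#' root estimate and the covariance is weighted by the inverse
#' Brownian-motion covariance implied by the phylogeny; in `"pca"` mode the
#' tree is ignored (identity weighting), the sensitivity variant.
#'
#' @slot mean the (phylogenetic) mean vector, one entry per element.
#' @slot eigenvectors orthonormal element-by-axis matrix, pPC1 first,
#'   each axis oriented to positive coefficient sum.
#' @slot eigenvalues nonincreasing, nonnegative.
#' @slot scores species-by-axis matrix of deviations projected on the axes.
#' @slot varianceFraction per-axis fraction of the total eigenvalue sum.
#' @slot mode `"ppca"` or `"pca"`.
#' @export
setClass("PPCAResult",
  representation(mean = "numeric", eigenvectors = "matrix",
                 eigenvalues = "numeric", scores = "matrix",
                 varianceFraction = "numeric", mode = "character"))

setValidity("PPCAResult", function(object) {
  V <- object@eigenvectors
  msgs <- character()
  if (max(abs(crossprod(V) - diag(ncol(V)))) > 1e-8)
    msgs <- c(msgs, "eigenvectors must be orthonormal")
  if (any(diff(object@eigenvalues) > 1e-10))
    msgs <- c(msgs, "eigenvalues must be nonincreasing")
  if (abs(sum(object@varianceFraction) - 1) > 1e-8)
    msgs <- c(msgs, "variance fractions must sum to 1")
  if (!object@mode %in% c("ppca", "pca"))
    msgs <- c(msgs, "mode must be 'ppca' or 'pca'")
  if (length(msgs)) msgs else TRUE
})

#' Alignment test between two allometric axes
#'
#' Observed angle \eqn{\Theta} between two estimated axes together with a
#' bootstrap distribution of angles from datasets modified to share one true
#' axis (forced perfect alignment). `aligned` is `TRUE` when the observed
#' angle does not exceed the one-sided 95% quantile of that null.
#'
#' @slot label comparison label, e.g. `"ont-Ant"`.
#' @slot thetaObs observed angle, degrees.
#' @slot nullAngles bootstrap null angles, degrees.
#' @slot ci95Upper 95% quantile of the null, degrees.
#' @slot aligned `thetaObs <= ci95Upper`.
#' @slot B,seed bootstrap iteration count and RNG seed.
#' @export
setClass("AlignmentTest",
  representation(label = "character", thetaObs = "numeric",
                 nullAngles = "numeric", ci95Upper = "numeric",
                 aligned = "logical", B = "integer", seed = "integer"))

setValidity("AlignmentTest", function(object) {
  msgs <- character()
  if (object@B < 100)
    msgs <- c(msgs, "bootstrap count B must be at least 100")
  if (any(object@nullAngles < 0))
    msgs <- c(msgs, "null angles must be nonnegative")
  if (!identical(object@aligned, object@thetaObs <= object@ci95Upper))
    msgs <- c(msgs, "aligned must equal thetaObs <= ci95Upper")
  if (length(msgs)) msgs else TRUE
})
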