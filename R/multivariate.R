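#' @include AllGenerics.R measurements.R
NULL

.newAllometricVector <- function(v, elements, source, variance_fraction,
                                 n, label = "") {
  new("AllometricVector",
      coefficients = stats::setNames(as.numeric(v), as.character(elements)),
      source = source, varianceFraction = as.numeric(variance_fraction),
      nUsed = as.integer(n), label = as.character(label))
}

#' @rdname AllometricVector-class
#' @export
setMethod("vectorCoefficients", "AllometricVector",
          function(x) x@coefficients)

#' @rdname AllometricVector-class
#' @export
setMethod("varianceFraction", "AllometricVector",
          function(x) x@varianceFraction)

setMethod("show", "AllometricVector", function(object) {
  cat(sprintf("AllometricVector [%s]%s: %.1f%% of variance, n = %d\n",
              object@source,
              if (nzchar(object@label)) paste0(" ", object@label) else "",
              100 * object@varianceFraction, object@nUsed))
  print(round(object@coefficients, 4))
})

#' Allometric vector of one group of observations
#'
#' The first principal component of the column-centered log bone-length
#' matrix, computed by singular value decomposition, normalized to unit
#' norm and oriented so the coefficient sum is positive. Its coefficients
#' express each element's share of growth along the major axis of
#' covariation; a coefficient above `p^-0.5` marks positive allometry of
#' that element.
#'
#' @param X log bone-length matrix, observations in rows, or a log-scale
#'   complete [LimbMeasurements] object (all specimens pooled).
#' @param label free-text label for the vector.
#' @param source provenance tag, see [AllometricVector-class].
#' @return an [AllometricVector-class] object.
#' @export
allometricVector <- function(X, label = "", source = "species PC1") {
  if (is(X, "LimbMeasurements")) {
    if (!isLogScale(X)) stop("log-transform the table first")
    X <- measurementMatrix(X)
  }
  X <- as.matrix(X)
  if (nrow(X) < ncol(X) + 1L)
    warning("only ", nrow(X), " rows for ", ncol(X),
            " elements; the allometric vector will be imprecise")
  r <- .pc1(X)
  .newAllometricVector(r$vector, colnames(X), source, r$variance_fraction,
                       nrow(X), label)
}

## Split a log-scale, complete table into per-species matrices.
.speciesMatrices <- function(x, min_rows = 2L) {
  stopifnot(is(x, "LimbMeasurements"))
  if (!isLogScale(x)) stop("log-transform the table first")
  M <- measurementMatrix(x)
  if (anyNA(M)) stop("table has missing cells; impute first")
  sp <- speciesOf(x)
  out <- lapply(split(seq_len(nrow(M)), factor(sp, levels = unique(sp))),
                function(i) M[i, , drop = FALSE])
  small <- names(out)[vapply(out, nrow, 1L) < min_rows]
  if (length(small))
    stop("species with fewer than ", min_rows, " specimens: ",
         paste(small, collapse = ", "))
  out
}

#' Per-species allometric vectors
#'
#' @param x a log-scale, complete [LimbMeasurements] object.
#' @return named list of [AllometricVector-class] objects, one per species.
#' @export
speciesVectors <- function(x) {
  mats <- .speciesMatrices(x)
  out <- lapply(names(mats), function(s)
    allometricVector(mats[[s]], label = s, source = "species PC1"))
  stats::setNames(out, names(mats))
}

#' Angle between two allometric vectors
#'
#' \eqn{\Theta = \arccos(v_1 \cdot v_2)} in degrees, the inner product
#' clamped to `[-1, 1]`. Vectors must share element ordering; comparing a
#' forelimb (p = 6) with a hindlimb (p = 7) vector is an error.
#'
#' @param v1,v2 [AllometricVector-class] objects or unit numeric vectors.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angleBetween <- function(v1, v2) {
  a <- if (is(v1, "AllometricVector")) vectorCoefficients(v1) else v1
  b <- if (is(v2, "AllometricVector")) vectorCoefficients(v2) else v2
  if (length(a) != length(b))
    stop("element sets differ (p = ", length(a), " vs p = ", length(b),
         "); are these the same limb?")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b)))
    stop("element orderings differ: ", paste(names(a), collapse = ","),
         " vs ", paste(names(b), collapse = ","))
  .angleDeg(a, b)
}

.angleMatrixOf <- function(coefList) {
  n <- length(coefList)
  A <- matrix(0, n, n, dimnames = list(names(coefList), names(coefList)))
  if (n > 1)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      A[i, j] <- A[j, i] <- .angleDeg(coefList[[i]], coefList[[j]])
    }
  A
}

## PC1 of a bootstrap resample; a resample that happens to have zero
## variance (all rows identical, possible on tiny noiseless fixtures) falls
## back to the full-sample axis instead of aborting the whole bootstrap.
.pc1Boot <- function(M, fallback)
  tryCatch(.pc1(M)$vector, error = function(e) fallback)

.makeAngleTestSet <- function(angles, nullq = NULL, B = 0L, seed = NA_integer_) {
  n <- nrow(angles)
  labs <- rownames(angles)
  ij <- which(upper.tri(angles), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  theta <- angles[ij]
  q95 <- if (is.null(nullq)) rep(NA_real_, nrow(ij)) else nullq
  pairs <- S4Vectors::DataFrame(
    label1 = labs[ij[, 1L]], label2 = labs[ij[, 2L]],
    theta_deg = theta, null_q95_deg = q95,
    exceeds_null = !is.na(q95) & theta > q95)
  new("AngleTestSet", pairs = pairs, angles = angles,
      meanAngle = if (nrow(ij)) mean(theta) else NA_real_,
      B = as.integer(B), seed = as.integer(seed))
}

#' @rdname AngleTestSet-class
#' @export
setMethod("angleMatrix", "AngleTestSet", function(x) x@angles)

#' @rdname AngleTestSet-class
#' @export
setMethod("meanAngle", "AngleTestSet", function(x) x@meanAngle)

setMethod("show", "AngleTestSet", function(object) {
  np <- nrow(object@pairs)
  cat(sprintf("AngleTestSet: %d vectors, %d unordered pairs, mean angle %.2f deg\n",
              nrow(object@angles), np, object@meanAngle))
  if (object@B > 0)
    cat(sprintf("  bootstrap null: B = %d, %d/%d pairs exceed their 95%% quantile\n",
                object@B, sum(object@pairs$exceeds_null), np))
})

#' Pairwise angles between allometric vectors
#'
#' Symmetric matrix of angles between every unordered pair of vectors
#' (zero diagonal) plus their mean; `n` vectors give `choose(n, 2)` pairs.
#'
#' @param vectors list of [AllometricVector-class] objects (2 or more),
#'   named or labelled.
#' @return an [AngleTestSet-class] without a bootstrap null
#'   (`null_q95_deg` is `NA`); see [sharedAllometryNull()] for the test.
#' @export
pairwiseAngles <- function(vectors) {
  if (length(vectors) < 2L) stop("need at least two vectors")
  coefs <- lapply(vectors, function(v)
    if (is(v, "AllometricVector")) vectorCoefficients(v) else v)
  if (is.null(names(coefs)))
    names(coefs) <- vapply(vectors, function(v)
      if (is(v, "AllometricVector")) v@label else "", "")
  .makeAngleTestSet(.angleMatrixOf(coefs))
}

#' Common (pooled within-species) allometric vector, cPC1
#'
#' Centers each species' log matrix at its own species mean, stacks the
#' centered matrices, and takes the first principal component of the pooled
#' matrix. Between-species mean differences are removed, so cPC1 captures
#' the shared within-species (ontogenetic) axis of covariation.
#'
#' @param x a log-scale complete [LimbMeasurements] object, or a list of
#'   per-species log matrices (each with 2 or more rows).
#' @return an [AllometricVector-class] with source `"common cPC1"`.
#' @export
commonAllometricVector <- function(x) {
  mats <- if (is(x, "LimbMeasurements")) .speciesMatrices(x) else x
  if (length(mats) < 2L) stop("need at least two species")
  few <- names(mats)[vapply(mats, nrow, 1L) < 2L]
  if (length(few))
    stop("species with fewer than 2 rows: ", paste(few, collapse = ", "))
  pooled <- do.call(rbind, lapply(mats, function(M)
    sweep(as.matrix(M), 2L, colMeans(M), "-")))
  r <- .pc1(pooled)
  .newAllometricVector(r$vector, colnames(pooled), "common cPC1",
                       r$variance_fraction, nrow(pooled), "cPC1")
}

#' Bootstrap test of the allometric vector against multivariate isometry
#'
#' Resamples observations with replacement `B` times, recomputes the
#' oriented first principal component each time, and forms per-element
#' percentile 95% confidence intervals of the coefficients. An element is
#' classified as positively (negatively) allometric when its interval lies
#' entirely above (below) the isometry value `p^-0.5`, and isometric
#' otherwise.
#'
#' @param X log matrix (observations by elements) or a log-scale complete
#'   [LimbMeasurements] object.
#' @param B bootstrap iterations (at least 100; 1000 by default).
#' @param seed integer RNG seed.
#' @return an [IsometryTest-class] object.
#' @export
isometryBootstrap <- function(X, B = 1000L, seed = 1L) {
  if (is(X, "LimbMeasurements")) {
    if (!isLogScale(X)) stop("log-transform the table first")
    X <- measurementMatrix(X)
  }
  X <- as.matrix(X)
  if (B < 100L) stop("B must be at least 100")
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L)
    warning("only ", n, " rows for ", p, " elements")
  obs <- .pc1(X)$vector
  set.seed(seed)
  boot <- matrix(NA_real_, B, p)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- .pc1Boot(X[idx, , drop = FALSE], obs)
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975))
  iso <- 1 / sqrt(p)
  cls <- ifelse(ci[1L, ] > iso, "positive",
                ifelse(ci[2L, ] < iso, "negative", "isometry"))
  tab <- S4Vectors::DataFrame(
    element = colnames(X), coefficient = obs,
    ci_lower = ci[1L, ], ci_upper = ci[2L, ], classification = cls)
  new("IsometryTest", table = tab, isometryValue = iso,
      B = as.integer(B), seed = as.integer(seed))
}

setMethod("show", "IsometryTest", function(object) {
  cat(sprintf("IsometryTest: p^-0.5 = %.5f, B = %d\n",
              object@isometryValue, object@B))
  print(as.data.frame(object@table), digits = 4)
})

#' Dataset conforming to a shared allometric pattern
#'
#' Builds, from per-species log matrices, a modified dataset in which every
#' species has exactly the common axis `v_c` as its true major axis while
#' keeping each species' mean, its score spread along the axis, and the
#' norm of every observation's off-axis residual. For species `s` with
#' estimated axis `v_s`: centered rows are split into the score on the
#' common axis and the residual about the species' own PC1; the residual is
#' transported into the orthogonal complement of `v_c` by the minimal
#' rotation carrying `v_s` onto `v_c` (norm-preserving), and the parts are
#' reassembled around the species mean.
#'
#' This construction is deliberately isolated here so an alternative recipe
#' for the shared-pattern null can be swapped in without touching
#' [sharedAllometryNull()].
#'
#' @param mats named list of per-species log matrices.
#' @param v_c common unit axis (e.g. from [commonAllometricVector()]).
#' @return named list of modified matrices, same shapes as the input.
#' @export
conformingDataset <- function(mats, v_c) {
  v_c <- .unitize(if (is(v_c, "AllometricVector"))
    vectorCoefficients(v_c) else v_c)
  lapply(mats, function(M) {
    M <- as.matrix(M)
    ctr <- colMeans(M)
    Xc <- sweep(M, 2L, ctr, "-")
    v_s <- .pc1(M)$vector
    Q <- rotationAligning(v_s, v_c)
    scores <- drop(Xc %*% v_c)
    resid <- Xc - drop(Xc %*% v_s) %o% v_s     # off-axis part, in v_s-perp
    conf <- scores %o% v_c + resid %*% t(Q)    # transported into v_c-perp
    sweep(conf, 2L, ctr, "+")
  })
}

#' Pairwise-angle test against a shared-allometry bootstrap null
#'
#' Tests, for every pair of species, whether the observed angle between
#' their allometric vectors is larger than expected if all species shared
#' one ontogenetic allometry. A conforming dataset with exactly that
#' property is built by [conformingDataset()] around the common axis cPC1;
#' each bootstrap iterate resamples specimens within every species from the
#' conforming data, re-estimates all per-species PC1s, and records all
#' pairwise angles. A pair whose observed angle exceeds the 95% quantile of
#' its own null distribution deviates significantly from the shared
#' pattern.
#'
#' @param x log-scale complete [LimbMeasurements] or named list of
#'   per-species log matrices.
#' @param B bootstrap iterations (at least 100; 1000 by default).
#' @param seed integer RNG seed.
#' @return an [AngleTestSet-class] with per-pair null quantiles filled in.
#' @export
sharedAllometryNull <- function(x, B = 1000L, seed = 1L) {
  if (B < 100L) stop("B must be at least 100")
  mats <- if (is(x, "LimbMeasurements")) .speciesMatrices(x) else x
  if (length(mats) < 2L) stop("need at least two species")
  vc <- vectorCoefficients(commonAllometricVector(mats))
  obs <- .angleMatrixOf(lapply(mats, function(M) .pc1(M)$vector))
  conf <- conformingDataset(mats, vc)
  nspecies <- length(conf)
  ns <- vapply(conf, nrow, 1L)
  ij <- which(upper.tri(obs), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  confAxes <- lapply(conf, function(M) .pc1(M)$vector)
  set.seed(seed)
  nullAngles <- matrix(NA_real_, B, nrow(ij))
  vhat <- vector("list", nspecies)
  for (b in seq_len(B)) {
    for (s in seq_len(nspecies)) {
      idx <- sample.int(ns[s], ns[s], replace = TRUE)
      vhat[[s]] <- .pc1Boot(conf[[s]][idx, , drop = FALSE], confAxes[[s]])
    }
    nullAngles[b, ] <- vapply(seq_len(nrow(ij)), function(k)
      .angleDeg(vhat[[ij[k, 1L]]], vhat[[ij[k, 2L]]]), 0)
  }
  q95 <- apply(nullAngles, 2L, stats::quantile, probs = 0.95)
  .makeAngleTestSet(obs, nullq = q95, B = B, seed = seed)
}

#' Allometric space: ordination of species by their allometric vectors
#'
#' A second PCA in which each species' allometric vector is one
#' observation. Species with similar patterns of relative bone growth plot
#' close together; an outlier species with a deviant growth pattern takes
#' an extreme PC1 score.
#'
#' @param vectors list of 3 or more per-species [AllometricVector-class]
#'   objects (or unit coefficient vectors), named by species.
#' @return an [AllometricSpace-class] with species scores and element
#'   loadings.
#' @export
allometricSpace <- function(vectors) {
  if (length(vectors) < 3L) stop("need at least three vectors")
  coefs <- lapply(vectors, function(v)
    if (is(v, "AllometricVector")) vectorCoefficients(v) else v)
  V <- do.call(rbind, coefs)
  if (is.null(rownames(V))) rownames(V) <- names(vectors)
  ctr <- colMeans(V)
  Vc <- sweep(V, 2L, ctr, "-")
  sv <- svd(Vc)
  k <- ncol(sv$v)
  scores <- Vc %*% sv$v
  colnames(scores) <- colnames(sv$v) <- paste0("PC", seq_len(k))
  rownames(sv$v) <- colnames(V)
  tot <- sum(sv$d^2)
  new("AllometricSpace", scores = scores, loadings = sv$v,
      varianceFraction = if (tot > 0) sv$d^2 / tot else rep(0, k))
}

setMethod("show", "AllometricSpace", function(object) {
  vf <- object@varianceFraction
  cat(sprintf("AllometricSpace: %d species, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(object@scores), 100 * vf[1L],
              if (length(vf) > 1L) 100 * vf[2L] else 0))
})
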