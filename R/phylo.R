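#' @include multivariate.R trees.R
NULL

## Core of the (phylogenetic) PCA of species means. X: species x p log
## means; Cinv: inverse Brownian covariance over the same species (identity
## for the standard-PCA variant). Returns the GLS mean, oriented
## eigenvectors, eigenvalues, scores and variance fractions.
.ppcaCore <- function(X, Cinv, mode) {
  n <- nrow(X); p <- ncol(X)
  one <- rep(1, n)
  denom <- sum(Cinv)
  a <- drop(crossprod(one, Cinv %*% X)) / denom       # GLS root estimate
  Xc <- X - matrix(a, n, p, byrow = TRUE)
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1)           # evolutionary cov
  R <- (R + t(R)) / 2
  eg <- eigen(R, symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(p)) {
    vj <- .orientPositive(V[, j])
    V[, j] <- vj
  }
  ## warn only when the *leading* axis is ambiguous; ties further down the
  ## spectrum are common (rank-deficient bootstrap resamples) and harmless
  if (p > 1 && eg$values[1L] - eg$values[2L] <
        1e-10 * max(abs(eg$values[1L]), 1e-300))
    warning("leading eigenvalues are near-degenerate; ",
            "the major axis is not uniquely defined")
  scores <- Xc %*% V
  ax <- paste0(if (mode == "ppca") "pPC" else "PC", seq_len(p))
  dimnames(V) <- list(colnames(X), ax)
  dimnames(scores) <- list(rownames(X), ax)
  tot <- sum(eg$values)
  new("PPCAResult", mean = stats::setNames(a, colnames(X)),
      eigenvectors = V, eigenvalues = eg$values, scores = scores,
      varianceFraction = if (tot > 0) eg$values / tot else rep(0, p),
      mode = mode)
}

#' Phylogenetic PCA of species means
#'
#' Principal components of the evolutionary covariance of log species
#' means under a Brownian-motion model on the tree: the mean is the
#' generalized-least-squares estimate at the root,
#' `a = (1'C^-1 1)^-1 1'C^-1 X`, the covariance is
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` with `C` the shared-path-length
#' matrix from [phyloVCV()], and species scores are the projections of the
#' deviations `X - 1a` on the eigenvectors. Covariance (not correlation)
#' mode is used throughout since all variables are same-unit log lengths.
#' The leading axis, pPC1, is the evolutionary allometric vector.
#'
#' @param means log-scale species-mean [LimbMeasurements] (one specimen per
#'   species) or a species-by-element log matrix with species rownames.
#' @param tree rooted [ape::phylo] tree; pruned internally to the species
#'   of `means`, whose set must be contained in the tips.
#' @return a [PPCAResult-class] with `mode = "ppca"`.
#' @export
phyloPCA <- function(means, tree) {
  X <- .meansMatrix(means)
  .checkTree(tree)
  missing <- setdiff(rownames(X), tree$tip.label)
  if (length(missing))
    stop("species not among the tree tips: ",
         paste(missing, collapse = ", "))
  tr <- pruneTreeTo(tree, rownames(X))
  C <- phyloVCV(tr)[rownames(X), rownames(X)]
  Cinv <- tryCatch(solve(C),
                   error = function(e) stop("singular phylogenetic ",
                                            "covariance: ",
                                            conditionMessage(e)))
  .ppcaCore(X, Cinv, "ppca")
}

#' Standard-PCA sensitivity variant
#'
#' Identical to [phyloPCA()] with the phylogenetic covariance replaced by
#' the identity: the ordinary mean and sample covariance of species means.
#' Used to check that conclusions do not hinge on the phylogenetic
#' weighting; on a star tree with equal branch lengths the two coincide.
#'
#' @inheritParams phyloPCA
#' @return a [PPCAResult-class] with `mode = "pca"`.
#' @export
standardPCAVariant <- function(means) {
  X <- .meansMatrix(means)
  .ppcaCore(X, diag(nrow(X)), "pca")
}

.meansMatrix <- function(means) {
  if (is(means, "LimbMeasurements")) {
    if (!isLogScale(means)) stop("log-transform the species means first")
    X <- measurementMatrix(means)
    rownames(X) <- speciesOf(means)
  } else X <- as.matrix(means)
  if (anyNA(X)) stop("species means contain missing values")
  if (is.null(rownames(X))) stop("species rownames are required")
  if (anyDuplicated(rownames(X))) stop("one row per species is required")
  X
}

#' @rdname axisVector
#' @export
setMethod("axisVector", "PPCAResult", function(x, which = 1L) {
  .newAllometricVector(
    x@eigenvectors[, which],
    rownames(x@eigenvectors),
    if (x@mode == "ppca") "evolutionary pPC1" else "evolutionary PC1",
    x@varianceFraction[which], nrow(x@scores),
    colnames(x@eigenvectors)[which])
})

#' @rdname PPCAResult-class
#' @param x a `PPCAResult`.
#' @export
setMethod("varianceFraction", "PPCAResult", function(x) x@varianceFraction)

setMethod("show", "PPCAResult", function(object) {
  cat(sprintf("PPCAResult (%s): %d species x %d elements\n",
              object@mode, nrow(object@scores), length(object@mean)))
  vf <- object@varianceFraction
  cat(sprintf("  axis 1: %.2f%% of variance; axis 2: %.2f%%\n",
              100 * vf[1L], if (length(vf) > 1L) 100 * vf[2L] else 0))
})

#' Evolutionary allometric vectors per major group, with angle tests
#'
#' Runs a phylogenetic PCA (or its standard variant) separately within each
#' major biogeographic group, extracts each group's leading axis, and
#' compares the axes pairwise. Significance of each between-group angle is
#' assessed against a bootstrap null in which the groups share one true
#' axis: group deviations from their GLS mean are rotated so every group's
#' leading axis coincides with the common (average) axis, then each
#' group's phylogenetically whitened deviations are resampled with
#' replacement (they are i.i.d. under the Brownian model) and the axes
#' re-estimated on the group's own tree covariance.
#'
#' @param means log-scale species-mean [LimbMeasurements] or matrix with
#'   species rownames.
#' @param tree rooted [ape::phylo] covering all species.
#' @param groups named character vector (species to group) from
#'   [readGroupMap()]; species mapped to `"other"` are dropped.
#' @param mode `"ppca"` (default) or `"pca"` for the sensitivity variant.
#' @param B bootstrap iterations for the angle null (at least 100);
#'   `B = 0` skips the null.
#' @param seed integer RNG seed.
#' @param min_species groups smaller than this are dropped with a warning
#'   (default `p + 1`); groups below `3 p` species trigger a precision
#'   warning.
#' @return list with `ppca` (named list of per-group [PPCAResult-class]),
#'   `vectors` (per-group [AllometricVector-class]) and `angles` (an
#'   [AngleTestSet-class]).
#' @export
groupEvolutionaryVectors <- function(means, tree, groups,
                                     mode = c("ppca", "pca"),
                                     B = 1000L, seed = 1L,
                                     min_species = NULL) {
  mode <- match.arg(mode)
  X <- .meansMatrix(means)
  p <- ncol(X)
  if (is.null(min_species)) min_species <- p + 1L
  sp <- rownames(X)
  unmapped <- setdiff(sp, names(groups))
  if (length(unmapped))
    stop("species not in the group map: ", paste(unmapped, collapse = ", "))
  g <- groups[sp]
  keep <- g != "other"
  glev <- unique(g[keep])
  parts <- split(sp[keep], factor(g[keep], levels = glev))
  small <- names(parts)[vapply(parts, length, 1L) < min_species]
  if (length(small)) {
    warning("group(s) with fewer than ", min_species, " species dropped: ",
            paste(small, collapse = ", "))
    parts <- parts[setdiff(names(parts), small)]
  }
  if (!length(parts)) stop("no group has enough species")
  tight <- names(parts)[vapply(parts, length, 1L) < 3L * p]
  if (length(tight))
    warning("group(s) with fewer than ", 3L * p,
            " species; axes will be imprecise: ",
            paste(tight, collapse = ", "))
  fitOne <- function(spp) {
    Xg <- X[spp, , drop = FALSE]
    if (mode == "ppca") phyloPCA(Xg, tree) else standardPCAVariant(Xg)
  }
  fits <- lapply(parts, fitOne)
  vecs <- lapply(fits, axisVector, which = 1L)
  if (length(parts) < 2L)
    return(list(ppca = fits, vectors = vecs,
                angles = NULL))
  obs <- .angleMatrixOf(lapply(vecs, vectorCoefficients))
  if (B == 0L)
    return(list(ppca = fits, vectors = vecs,
                angles = .makeAngleTestSet(obs)))
  if (B < 100L) stop("B must be at least 100 (or 0 to skip the null)")
  ## Shared-axis null: rotate every group's deviations onto the common axis
  axes <- vapply(vecs, vectorCoefficients, numeric(p))
  vC <- .orientPositive(.unitize(rowMeans(axes)))
  Call <- if (mode == "ppca") phyloVCV(pruneTreeTo(tree, sp[keep])) else NULL
  conf <- lapply(names(parts), function(gn) {
    f <- fits[[gn]]
    dev <- f@scores %*% t(f@eigenvectors)       # deviations from GLS mean
    Q <- rotationAligning(vectorCoefficients(vecs[[gn]]), vC)
    out <- dev %*% t(Q) + matrix(f@mean, nrow(dev), p, byrow = TRUE)
    rownames(out) <- rownames(f@scores)
    colnames(out) <- names(f@mean)
    out
  })
  names(conf) <- names(parts)
  booters <- lapply(conf, .makeAxisBooter, Call = Call, mode = mode)
  ij <- which(upper.tri(obs), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  set.seed(seed)
  nullAngles <- matrix(NA_real_, B, nrow(ij))
  for (b in seq_len(B)) {
    vhat <- lapply(booters, function(f) f())
    nullAngles[b, ] <- vapply(seq_len(nrow(ij)), function(k)
      .angleDeg(vhat[[ij[k, 1L]]], vhat[[ij[k, 2L]]]), 0)
  }
  q95 <- apply(nullAngles, 2L, stats::quantile, probs = 0.95)
  list(ppca = fits, vectors = vecs,
       angles = .makeAngleTestSet(obs, nullq = q95, B = B, seed = seed))
}

#' Correlation of leading-axis scores with body size
#'
#' Pearson correlation between each species' score on the leading
#' (p)PC1 axis and its log body-size proxy. A correlation near 1 licenses
#' reading the axis as an allometric (size) vector. When the axis loadings
#' are positive (the orientation convention), larger species score higher,
#' so the correlation sign is meaningful.
#'
#' @param ppca a [PPCAResult-class].
#' @param log_size named numeric vector of log size proxies per species
#'   (e.g. `sizeProxy()` of a log-scale species-mean table, named by
#'   species).
#' @return data.frame with `r`, `p_value`, `n`.
#' @export
correlateWithSize <- function(ppca, log_size) {
  sc <- ppca@scores[, 1L]
  if (is.null(names(log_size)))
    stop("log_size must be named by species")
  if (!setequal(names(log_size), rownames(ppca@scores)))
    stop("species sets differ between scores and sizes")
  log_size <- log_size[rownames(ppca@scores)]
  ct <- stats::cor.test(sc, log_size, method = "pearson")
  data.frame(r = unname(ct$estimate), p_value = ct$p.value,
             n = length(sc))
}
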