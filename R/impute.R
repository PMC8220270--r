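#' @include measurements.R
NULL

## EM-style iterative-PCA completion of one numeric matrix (rows =
## specimens). Missing cells are seeded with column means; each sweep fits a
## rank-k PCA to the completed, column-centered matrix and refills only the
## missing cells from the low-rank reconstruction, until the largest
## relative change of an imputed value falls below tol. Signal singular
## values are shrunk by the trailing-eigenvalue noise estimate (regularized
## iterative PCA): without the shrinkage the plain EM iteration can drift
## without converging when k approaches p and n is small, as imputed cells
## slide along near-flat directions of the fit. On a noiseless rank-k
## matrix the noise estimate is zero, the shrinkage vanishes, and the fixed
## point is the exact completion.
.imputeMatrix <- function(M, n_components, tol, max_iter) {
  miss <- is.na(M)
  if (!any(miss)) return(list(M = M, iter = 0L, converged = TRUE))
  if (any(colSums(!miss) == 0))
    stop("imputation scope has a fully missing element column; ",
         "enlarge the scope or drop the element")
  if (nrow(M) < n_components + 1L)
    stop("imputation scope has ", nrow(M), " rows; need at least ",
         n_components + 1L, " for rank-", n_components,
         " completion - use a larger scope or fewer components")
  n <- nrow(M)
  cm <- colMeans(M, na.rm = TRUE)
  X <- M
  X[miss] <- matrix(cm, n, ncol(M), byrow = TRUE)[miss]
  scale_ref <- max(abs(X[miss]), 1e-12)
  converged <- FALSE
  total <- 0L
  ## Warm-started rank sweep: converge the rank-1 model first, then refine
  ## with one extra component at a time. Starting straight at the target
  ## rank can freeze at the (arbitrary) initial fill whenever the filled
  ## matrix has rank <= k, because the reconstruction then reproduces it
  ## exactly; sweeping upward reaches the dominant-axis completion first
  ## and the numerical-rank cap keeps exactly-low-rank completions fixed.
  for (kk in seq_len(n_components)) {
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      total <- total + 1L
      ctr <- colMeans(X)
      Xc <- sweep(X, 2L, ctr, "-")
      sv <- svd(Xc)
      lam <- sv$d^2 / (n - 1)
      k <- min(kk, sum(sv$d > 1e-12 * sv$d[1L]))
      rec <- if (k > 0) {
        s2 <- if (k < length(lam)) mean(lam[(k + 1L):length(lam)]) else 0
        shrink <- pmax((lam[seq_len(k)] - s2) / lam[seq_len(k)], 0)
        sv$u[, seq_len(k), drop = FALSE] %*%
          ((sv$d[seq_len(k)] * shrink) *
             t(sv$v[, seq_len(k), drop = FALSE]))
      } else matrix(0, nrow(X), ncol(X))
      rec <- sweep(rec, 2L, ctr, "+")
      delta <- max(abs(rec[miss] - X[miss]) / pmax(abs(X[miss]), scale_ref))
      X[miss] <- rec[miss]
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  list(M = X, iter = total, converged = converged)
}

#' Impute missing bone lengths by iterative PCA
#'
#' Completes missing element cells with an EM-style iterative principal
#' component reconstruction (the NIPALS-family algorithm behind standard
#' PCA-imputation tools): missing cells are initialized at column means, a
#' rank-`n_components` PCA of the log-scale matrix is fit, missing cells are
#' refilled from the low-rank reconstruction, and the two steps alternate to
#' convergence. Observed cells are never altered. Imputation operates on the
#' log scale internally (growth is log-linear, so the low-rank model holds
#' there) and returns values on the scale of the input table.
#'
#' @param x a [LimbMeasurements] object.
#' @param scope `"per_species"` fits one model per species (the default for
#'   ontogenetic series, where covariation is species-specific);
#'   `"global"` fits a single model to all specimens (the default choice for
#'   adult tables with few specimens per species).
#' @param n_components rank of the completion model; default
#'   `min(4, p - 1)`.
#' @param tol relative-change convergence tolerance (default `1e-6`).
#' @param max_iter maximum sweeps; non-convergence warns and returns the
#'   best iterate.
#' @param seed unused by the (deterministic) algorithm; accepted so callers
#'   can treat all pipeline stages uniformly.
#' @return a complete [LimbMeasurements] object.
#' @export
imputeMissing <- function(x, scope = c("per_species", "global"),
                          n_components = NULL, tol = 1e-6,
                          max_iter = 500L, seed = NULL) {
  scope <- match.arg(scope)
  M <- measurementMatrix(x)
  if (!anyNA(M)) return(x)
  p <- ncol(M)
  if (is.null(n_components)) n_components <- min(4L, p - 1L)
  logscale <- isLogScale(x)
  W <- if (logscale) M else log(M)
  fill <- function(block) {
    res <- .imputeMatrix(block, n_components, tol, max_iter)
    if (!res$converged)
      warning("imputation did not converge within ", max_iter,
              " iterations; returning the final iterate")
    res$M
  }
  if (scope == "global") {
    W <- fill(W)
  } else {
    sp <- speciesOf(x)
    for (s in unique(sp)) {
      rows <- which(sp == s)
      if (anyNA(W[rows, , drop = FALSE])) {
        W[rows, ] <- tryCatch(
          fill(W[rows, , drop = FALSE]),
          error = function(e) stop("species '", s, "': ",
                                   conditionMessage(e), call. = FALSE))
      }
    }
  }
  out <- if (logscale) W else exp(W)
  miss <- is.na(M)
  M[miss] <- out[miss]   # observed cells pass through untouched
  A <- SummarizedExperiment::assay(x, "lengths")
  A[t(miss)] <- t(M)[t(miss)]
  SummarizedExperiment::assay(x, "lengths") <- A
  validObject(x)
  x
}
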