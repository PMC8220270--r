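#' @include trees.R
NULL

## Symmetric PSD square root via eigen-decomposition; tolerates the
## rank-deficient covariances used for rank-1-dominant simulations.
.matSqrt <- function(S, tol = 1e-10) {
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < -tol * max(abs(eg$values), 1))
    stop("covariance matrix is not positive semidefinite")
  ev <- pmax(eg$values, 0)
  eg$vectors %*% (sqrt(ev) * t(eg$vectors))
}

#' Simulate an ontogenetic measurement series
#'
#' Generates specimen-level bone lengths for several species growing along a
#' (nearly) shared multivariate allometric axis. For species `s` and
#' specimen `i`, a latent size `u` is drawn uniformly over `growth_range`
#' and the log element vector is
#' `anlage_intercepts[s, ] + u * v_s + noise`, with `v_s` the common unit
#' vector tilted by `perturbation_deg` degrees within a random plane (one
#' tilt per species) and i.i.d. Gaussian noise of standard deviation
#' `residual_sd` (log units). Spine length is generated so that the
#' log-log slope of total limb length against spine length equals
#' `slope_vs_spine` in expectation at mid-growth, making limbs grow faster
#' than the trunk when the slope exceeds 1. Element cells are then masked
#' missing-at-random at `missing_fraction`.
#'
#' The defaults emulate the design of an embryonic growth study in a lizard
#' radiation: 15 species, 25 specimens each (stages spanning early
#' limb-skeleton formation to hatchling), ~3% missing cells from fractured
#' bones, and bivariate slopes above 1.
#'
#' @param n_species,n_per_species numbers of species and of specimens per
#'   species.
#' @param elements element names (defines `p`); see [limbElements()].
#' @param common_vector true shared unit axis; default is the isometric
#'   vector `rep(p^-0.5, p)` tilted towards the long bones.
#' @param perturbation_deg degrees by which each species' true axis is
#'   tilted away from `common_vector` (0 = perfectly shared axis).
#' @param anlage_intercepts optional `n_species x p` matrix of log-mm
#'   starting sizes of the cartilaginous anlagen; by default species draw
#'   independent intercepts around element-typical sizes (long bones larger
#'   than metapodials and phalanges), giving species differences that are
#'   present before growth.
#' @param growth_range interval of the latent size variable (log units along
#'   the axis); default `c(0, 5)`, about an 8-fold elongation of each bone.
#' @param slope_vs_spine target log-log slope of total limb length on spine
#'   length, recycled across species.
#' @param residual_sd measurement/biological noise, log units.
#' @param missing_fraction fraction of element cells masked `NA` (< 0.5).
#' @param seed integer RNG seed; the output is fully reproducible.
#' @return a linear-scale [LimbMeasurements] object; the true per-species
#'   axes are attached as `metadata(x)$true_axes` (rows = species) and the
#'   common axis as `metadata(x)$true_common_vector`.
#' @export
#' @examples
#' x <- simulateOntogeny(n_species = 3, n_per_species = 10, seed = 1)
#' x
simulateOntogeny <- function(n_species = 15L, n_per_species = 25L,
                             elements = limbElements("forelimb"),
                             common_vector = NULL,
                             perturbation_deg = 0,
                             anlage_intercepts = NULL,
                             growth_range = c(0, 5),
                             slope_vs_spine = 1.3,
                             residual_sd = 0.05,
                             missing_fraction = 0.03,
                             seed = 1L) {
  p <- length(elements)
  if (missing_fraction < 0 || missing_fraction >= 0.5)
    stop("missing_fraction must lie in [0, 0.5)")
  if (diff(range(growth_range)) <= 0)
    stop("growth_range is degenerate (zero width)")
  if (is.null(common_vector)) {
    ## isometry plus mild positive allometry of the first two (long) bones
    common_vector <- rep(1, p); common_vector[1:2] <- 1.25
  }
  v0 <- .unitize(common_vector)
  if (length(v0) != p) stop("common_vector must have one entry per element")
  slope_vs_spine <- rep_len(slope_vs_spine, n_species)
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  if (is.null(anlage_intercepts)) {
    base <- log(c(0.8, 0.7, 0.35, rep(0.25, p - 3L)))  # element-typical mm
    anlage_intercepts <- matrix(rep(base, each = n_species), n_species, p) +
      matrix(stats::rnorm(n_species * p, sd = 0.15), n_species, p)
  }
  anlage_intercepts <- as.matrix(anlage_intercepts)
  stopifnot(nrow(anlage_intercepts) == n_species,
            ncol(anlage_intercepts) == p)
  axes <- t(vapply(seq_len(n_species),
                   function(s) .tiltVector(v0, perturbation_deg),
                   numeric(p)))
  rownames(axes) <- species
  n <- n_species * n_per_species
  L <- matrix(NA_real_, n, p, dimnames = list(NULL, as.character(elements)))
  logspine <- numeric(n)
  u_all <- numeric(n)
  spine_base <- log(5) + stats::rnorm(n_species, sd = 0.1)
  umid <- mean(growth_range)
  for (s in seq_len(n_species)) {
    rows <- (s - 1L) * n_per_species + seq_len(n_per_species)
    u <- stats::runif(n_per_species, growth_range[1L], growth_range[2L])
    u_all[rows] <- u
    mu <- matrix(anlage_intercepts[s, ], n_per_species, p, byrow = TRUE) +
      outer(u, axes[s, ])
    L[rows, ] <- mu + matrix(stats::rnorm(n_per_species * p,
                                          sd = residual_sd),
                             n_per_species, p)
    ## element weights at mid-growth give d log(total limb)/du, so dividing
    ## by the target slope puts the total-vs-spine log-log slope on target
    w <- exp(anlage_intercepts[s, ] + umid * axes[s, ])
    g <- sum(w / sum(w) * axes[s, ])
    logspine[rows] <- spine_base[s] + (g / slope_vs_spine[s]) * u +
      stats::rnorm(n_per_species, sd = residual_sd)
  }
  urel <- (u_all - growth_range[1L]) / diff(range(growth_range))
  stage <- 11 + floor(urel * 8.999)           # staging-table stages 11-19
  life_stage <- ifelse(stage >= 19, "hatchling", "embryo")
  if (missing_fraction > 0) {
    mask <- matrix(stats::runif(n * p) < missing_fraction, n, p)
    L[mask] <- NA_real_
  }
  out <- LimbMeasurements(exp(L),
                          specimen_id = sprintf("ind%04d", seq_len(n)),
                          species = rep(species, each = n_per_species),
                          life_stage = life_stage,
                          size_proxy = exp(logspine),
                          stage = stage,
                          elements = as.character(elements),
                          missing_cap = 0.5)
  S4Vectors::metadata(out)$true_common_vector <-
    stats::setNames(v0, as.character(elements))
  S4Vectors::metadata(out)$true_axes <- axes
  out
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Complete-sampling birth-death simulation with zero extinction, rescaled
#' to unit root-to-tip height; the result is ultrametric with tips labelled
#' `sp01, sp02, ...` to match [simulateOntogeny()].
#'
#' @param n_tips number of tips (at least 2).
#' @param seed integer RNG seed.
#' @return an ultrametric [ape::phylo] tree of height 1.
#' @export
simulateTree <- function(n_tips, seed = 1L) {
  if (n_tips < 2L) stop("need at least 2 tips")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

#' Rank-1-dominant trait covariance
#'
#' Builds a `p x p` PSD matrix placing fraction `rank1_weight` of the total
#' trace on the axis `axis` and spreading the remainder isotropically over
#' its orthogonal complement. Used to simulate evolution dominated by a
#' single (allometric) direction.
#'
#' @param axis dominant direction (any nonzero vector; normalized).
#' @param total_variance trace of the matrix (rate units per unit branch
#'   length).
#' @param rank1_weight fraction of the trace on `axis`, in `[0, 1]`.
#' @return a symmetric PSD matrix.
#' @export
rank1Covariance <- function(axis, total_variance = 1, rank1_weight = 0.95) {
  a <- .unitize(axis)
  p <- length(a)
  if (rank1_weight < 0 || rank1_weight > 1)
    stop("rank1_weight must lie in [0, 1]")
  P <- tcrossprod(a)
  total_variance * (rank1_weight * P +
                      if (p > 1) (1 - rank1_weight) / (p - 1) * (diag(p) - P)
                      else 0 * P)
}

#' Simulate species means under multivariate Brownian motion
#'
#' Tip states follow a matrix-normal model: `X = 1 root' + A Z B'` with
#' `A A' = C` the shared-path-length matrix of the tree and `B B' = Sigma`
#' the trait covariance, i.e. `vec(X) ~ MVN(1 (x) root, C (x) Sigma)`.
#' Values are log trait means (log mm); the returned table is on the log
#' scale with one "specimen" per species. The size proxy is generated as a
#' log centroid size proportional to each species' average log deviation
#' from the root, so that a rank-1-dominant `Sigma` with positive loadings
#' yields the tight size-axis correlation typical of evolutionary allometry.
#'
#' @param tree rooted [ape::phylo] tree whose tips name the species.
#' @param root_state length-`p` vector of log trait values at the root.
#' @param bm_covariance `p x p` PSD trait covariance per unit branch length
#'   (e.g. from [rank1Covariance()]).
#' @param elements element names for the columns.
#' @param seed integer RNG seed.
#' @return a log-scale [LimbMeasurements] of species means
#'   (`life_stage = "adult"`).
#' @export
simulateEvolution <- function(tree, root_state, bm_covariance,
                              elements = limbElements("forelimb"),
                              seed = 1L) {
  .checkTree(tree)
  p <- length(root_state)
  stopifnot(length(elements) == p,
            nrow(bm_covariance) == p, ncol(bm_covariance) == p)
  if (max(abs(bm_covariance - t(bm_covariance))) > 1e-8)
    stop("covariance matrix is not symmetric")
  C <- phyloVCV(tree)
  A <- .matSqrt(C)
  B <- .matSqrt(bm_covariance)
  set.seed(seed)
  n <- nrow(C)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- matrix(root_state, n, p, byrow = TRUE) + A %*% Z %*% t(B)
  dimnames(X) <- list(rownames(C), as.character(elements))
  logsize <- log(30) + rowMeans(X - matrix(root_state, n, p, byrow = TRUE))
  LimbMeasurements(X, specimen_id = rownames(C), species = rownames(C),
                   life_stage = "adult", size_proxy = logsize,
                   elements = as.character(elements), log_scale = TRUE)
}
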