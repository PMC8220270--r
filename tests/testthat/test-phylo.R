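test_that("phylogenetic PCA equals standard PCA on a star tree", {
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("s%02d:1", 1:20), collapse = ","), "):0;"))
  set.seed(19)
  X <- matrix(rnorm(20 * 6, sd = 0.4), 20, 6) +
    outer(rnorm(20), c(2, 2, 1, 1, 1, 1))
  dimnames(X) <- list(star$tip.label, fore6)
  pp <- phyloPCA(X, star)
  sp <- standardPCAVariant(X)
  expect_equal(pp@mean, sp@mean, tolerance = 1e-10)
  expect_equal(pp@eigenvectors, sp@eigenvectors, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(pp@scores, sp@scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(pp@eigenvalues, sp@eigenvalues, tolerance = 1e-10)
})

test_that("a 3-taxon fixture matches the hand-computed GLS mean and eigen solution", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  X <- matrix(c(1.0, 2.0,
                1.4, 2.6,
                0.2, 1.1), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("e1", "e2")))
  pp <- phyloPCA(X, tr)
  C <- matrix(c(2, 1, 0,
                1, 2, 0,
                0, 0, 2), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  o <- oraclePPCA(X, C)
  expect_equal(unname(pp@mean), unname(o$mean), tolerance = 1e-10)
  expect_equal(unname(pp@eigenvectors), unname(o$vectors),
               tolerance = 1e-10)
  expect_equal(unname(pp@eigenvalues), unname(o$values), tolerance = 1e-10)
  expect_equal(unname(pp@scores), unname(o$scores), tolerance = 1e-10)
})

test_that("phyloPCA agrees with the phytools reference implementation", {
  skip_if_not_installed("phytools")
  tr <- simulateTree(25, seed = 23)
  ev <- simulateEvolution(tr, rep(0, 6),
                          rank1Covariance(c(2, 2, 1, 1, 1, 1), 0.5, 0.9),
                          seed = 24)
  X <- measurementMatrix(ev)
  rownames(X) <- speciesOf(ev)
  pp <- phyloPCA(X, tr)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  # same axes up to sign, same eigenvalues
  for (j in 1:3) {
    expect_lt(min(angleBetween(pp@eigenvectors[, j], ref$Evec[, j]),
                  angleBetween(pp@eigenvectors[, j], -ref$Evec[, j])),
              1e-6)
  }
  expect_equal(unname(pp@eigenvalues), unname(diag(ref$Eval)),
               tolerance = 1e-8)
})

test_that("pPC1 recovers the dominant axis of a rank-1 Brownian model", {
  tr <- simulateTree(100, seed = 25)
  axis <- c(2, 2, 1, 1, 1, 1); axis <- axis / sqrt(sum(axis^2))
  ev <- simulateEvolution(tr, rep(0, 6),
                          rank1Covariance(axis, 0.5, 0.97), seed = 26)
  pp <- phyloPCA(ev, tr)
  expect_lt(angleBetween(axisVector(pp, 1), axis), 3)
  expect_gt(varianceFraction(pp)[1], 0.9)
})

test_that("scores are invariant to tip order and R stays PSD", {
  tr <- simulateTree(15, seed = 27)
  ev <- simulateEvolution(tr, rep(0, 6), rank1Covariance(rep(1, 6), 1, 0.8),
                          seed = 28)
  X <- measurementMatrix(ev)
  rownames(X) <- speciesOf(ev)
  pp1 <- phyloPCA(X, tr)
  perm <- sample(nrow(X))
  pp2 <- phyloPCA(X[perm, ], tr)
  expect_equal(pp1@scores[rownames(X), ], pp2@scores[rownames(X), ],
               tolerance = 1e-9)
  expect_gt(min(pp1@eigenvalues), -1e-10)
  expect_error(phyloPCA(X, pruneTreeTo(tr, rownames(X)[1:10])),
               "not among the tree tips")
})

test_that("degenerate trees with zero-length branches are refused", {
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  X <- matrix(c(1, 2, 1.5, 2.5), 2, 2,
              dimnames = list(c("A", "B"), c("e1", "e2")))
  expect_error(phyloPCA(X, tr0), "singular")
})

test_that("group evolutionary vectors report pairwise angles per group", {
  tr <- simulateTree(60, seed = 29)
  axis <- c(2, 2, 1, 1, 1, 1)
  ev <- simulateEvolution(tr, rep(0, 6), rank1Covariance(axis, 0.5, 0.95),
                          seed = 30)
  X <- measurementMatrix(ev); rownames(X) <- speciesOf(ev)
  groups <- setNames(rep(c("Ant", "MLpri", "MLsec"), each = 20),
                     rownames(X))
  res <- groupEvolutionaryVectors(X, tr, groups, B = 150, seed = 31)
  expect_named(res$vectors, c("Ant", "MLpri", "MLsec"))
  expect_equal(nrow(res$angles@pairs), 3L)
  # same generating covariance in all groups: small angles, nothing flagged
  expect_lt(meanAngle(res$angles), 10)
  expect_error(groupEvolutionaryVectors(X, tr, groups[1:30], B = 0),
               "not in the group map")
  # identical data in two groups gives a zero between-group angle
  expect_equal(angleBetween(
    axisVector(standardPCAVariant(X[1:20, ]), 1),
    axisVector(standardPCAVariant(X[1:20, ]), 1)), 0, tolerance = 1e-12)
})

test_that("group null calibration: identical Brownian covariance is rarely flagged", {
  set.seed(32)
  hits <- 0L; trials <- 60L
  tr <- simulateTree(44, seed = 33)
  groups <- setNames(rep(c("Ant", "MLsec"), each = 22),
                     sprintf("sp%02d", 1:44))
  for (r in seq_len(trials)) {
    ev <- simulateEvolution(tr, rep(0, 6),
                           rank1Covariance(c(2, 2, 1, 1, 1, 1), 0.5, 0.9),
                           seed = 100 + r)
    X <- measurementMatrix(ev); rownames(X) <- speciesOf(ev)
    res <- groupEvolutionaryVectors(X, tr, groups, B = 150,
                                    seed = 200 + r)
    hits <- hits + as.integer(res$angles@pairs$exceeds_null[1])
  }
  # expected 5% exceedance; binomial 99% bounds for 60 trials
  expect_lte(hits, 9L)
})

test_that("size correlations use the leading-axis scores", {
  tr <- simulateTree(40, seed = 35)
  axis <- rep(1, 6)
  ev <- simulateEvolution(tr, rep(log(10), 6),
                          rank1Covariance(axis, 0.5, 0.98), seed = 36)
  pp <- phyloPCA(ev, tr)
  sizes <- setNames(sizeProxy(ev), speciesOf(ev))
  res <- correlateWithSize(pp, sizes)
  expect_gt(res$r, 0.95)
  expect_lt(res$p_value, 0.001)
  # scores exactly proportional to size give r = 1
  fake <- setNames(pp@scores[, 1] * 2 + 5, rownames(pp@scores))
  expect_equal(correlateWithSize(pp, fake)$r, 1, tolerance = 1e-12)
  # permuted sizes agree with the direct formula
  set.seed(37)
  perm <- setNames(sample(sizes), names(sizes))
  r1 <- correlateWithSize(pp, perm)$r
  expect_equal(r1, cor(pp@scores[, 1], perm[rownames(pp@scores)]),
               tolerance = 1e-12)
  expect_error(correlateWithSize(pp, unname(sizes)), "named")
})
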