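test_that("the allometric vector is the oriented leading principal axis", {
  # data varying along a single known direction
  u <- c(3, 1, 2, 1, 1, 1); u <- u / sqrt(sum(u^2))
  X <- outer(seq(-2, 2, length.out = 9), u)
  colnames(X) <- fore6
  av <- allometricVector(X)
  expect_s4_class(av, "AllometricVector")
  expect_equal(unname(vectorCoefficients(av)), u, tolerance = 1e-12)
  expect_equal(varianceFraction(av), 1)
  # isometric growth: every coefficient equals p^-0.5
  Xi <- outer(seq(0, 3, length.out = 8), rep(1, 6))
  colnames(Xi) <- fore6
  iso <- vectorCoefficients(allometricVector(Xi))
  expect_equal(unname(iso), rep(1 / sqrt(6), 6), tolerance = 1e-12)
  expect_equal(unname(iso)[1], 0.40825, tolerance = 1e-5)
  expect_error(allometricVector(matrix(1, 5, 3)), "variance")
  expect_warning(allometricVector(X[1:4, ]), "imprecise")
})

test_that("the SVD axis agrees with brute-force eigen-decomposition", {
  set.seed(60)
  for (p in c(3, 6, 10)) {
    X <- matrix(rnorm(12 * p), 12, p) %*%
      (diag(p) + 0.5 * matrix(runif(p * p), p, p))
    colnames(X) <- paste0("e", seq_len(p))
    expect_equal(unname(vectorCoefficients(allometricVector(X))),
                 oraclePC1(X), tolerance = 1e-10)
  }
  # the 5 x 3 toy case spelled out
  T53 <- matrix(c(1, 2, 3, 2, 4.1, 5.9, 3, 6.2, 9.1,
                  4, 8.1, 11.8, 5, 9.9, 15.2), 5, 3, byrow = TRUE)
  colnames(T53) <- c("a", "b", "c")
  expect_equal(unname(vectorCoefficients(allometricVector(T53))),
               oraclePC1(T53), tolerance = 1e-10)
})

test_that("angles behave like arc cosines of inner products", {
  expect_equal(angleBetween(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angleBetween(c(1, 0), c(0, 1)), 90)
  expect_equal(angleBetween(c(1, 0), c(sqrt(2) / 2, sqrt(2) / 2)), 45,
               tolerance = 1e-12)
  expect_error(angleBetween(rep(1, 6), rep(1, 7)), "same limb")
  # size scaling (adding a constant to every log value) leaves angles alone
  set.seed(3)
  A <- matrix(rnorm(60), 10, 6); colnames(A) <- fore6
  B <- matrix(rnorm(60), 10, 6); colnames(B) <- fore6
  a0 <- angleBetween(allometricVector(A), allometricVector(B))
  expect_equal(angleBetween(allometricVector(A + 5), allometricVector(B)),
               a0, tolerance = 1e-10)
  # row order does not matter
  expect_equal(angleBetween(allometricVector(A[sample(10), ]),
                            allometricVector(B)), a0, tolerance = 1e-10)
})

test_that("pairwise angles enumerate all unordered pairs", {
  set.seed(14)
  vecs <- lapply(1:15, function(i) {
    X <- matrix(rnorm(60), 10, 6); colnames(X) <- fore6
    allometricVector(X, label = paste0("sp", i))
  })
  names(vecs) <- paste0("sp", 1:15)
  pa <- pairwiseAngles(vecs)
  expect_equal(nrow(pa@pairs), 105L)
  expect_equal(unname(angleMatrix(pa)), unname(t(angleMatrix(pa))))
  # identical vectors: mean angle zero
  same <- rep(vecs[1], 4); names(same) <- paste0("v", 1:4)
  expect_equal(meanAngle(pairwiseAngles(same)), 0)
  # three fixed vectors against a hand-computed average
  v1 <- c(1, 0, 0); v2 <- c(0, 1, 0); v3 <- c(sqrt(2) / 2, sqrt(2) / 2, 0)
  pa3 <- pairwiseAngles(list(a = v1, b = v2, c = v3))
  expect_equal(meanAngle(pa3), (90 + 45 + 45) / 3, tolerance = 1e-12)
  expect_error(pairwiseAngles(vecs[1]), "at least two")
})

test_that("the common vector pools within-species variation", {
  u <- c(2, 2, 1, 1, 1, 1); u <- u / sqrt(sum(u^2))
  X <- outer(seq(0, 3, length.out = 12), u) + 0.3
  colnames(X) <- fore6
  # identical data in every species: cPC1 equals each species PC1
  cp <- commonAllometricVector(list(a = X, b = X, c = X))
  expect_equal(unname(vectorCoefficients(cp)), u, tolerance = 1e-10)
  expect_equal(cp@source, "common cPC1")
  # two species tilted symmetrically +/-10 deg around u: cPC1 near u
  b1 <- c(-2, 2, 1, -1, 1, -1); b1 <- b1 - sum(b1 * u) * u
  b1 <- b1 / sqrt(sum(b1^2))
  th <- 10 * pi / 180
  va <- cos(th) * u + sin(th) * b1
  vb <- cos(th) * u - sin(th) * b1
  s <- seq(-2, 2, length.out = 40)
  Ma <- outer(s, va); Mb <- outer(s, vb)
  colnames(Ma) <- colnames(Mb) <- fore6
  cp2 <- commonAllometricVector(list(a = Ma, b = Mb))
  expect_lt(angleBetween(vectorCoefficients(cp2), u), 1)
  expect_error(commonAllometricVector(list(a = X)), "two species")
  expect_error(commonAllometricVector(
    list(a = X, b = X[1, , drop = FALSE])), "fewer than 2")
})

test_that("isometry bootstrap classifies coefficients against p^-0.5", {
  # noiseless isometric growth: degenerate CIs exactly at p^-0.5
  Xi <- outer(seq(0, 3, length.out = 30), rep(1, 6))
  colnames(Xi) <- fore6
  iso <- isometryBootstrap(Xi, B = 200, seed = 1)
  expect_equal(iso@isometryValue, 1 / sqrt(6))
  expect_true(all(iso@table$classification == "isometry"))
  expect_lt(max(abs(iso@table$ci_lower - 1 / sqrt(6))), 1e-10)
  expect_lt(max(abs(iso@table$ci_upper - 1 / sqrt(6))), 1e-10)
  # one element growing 1.5x faster: flagged positively allometric
  set.seed(2)
  s <- runif(100, 0, 3)
  X <- outer(s, c(1.5, rep(1, 5))) + matrix(rnorm(600, sd = 0.05), 100, 6)
  colnames(X) <- fore6
  t2 <- isometryBootstrap(X, B = 500, seed = 3)
  expect_identical(t2@table$classification[1], "positive")
  expect_true(all(t2@table$classification[2:6] %in%
                    c("negative", "isometry")))
  expect_error(isometryBootstrap(X, B = 50), "at least 100")
  # bit-reproducible under a fixed seed
  t3 <- isometryBootstrap(X, B = 500, seed = 3)
  expect_identical(t2@table$ci_lower, t3@table$ci_lower)
})

test_that("the conforming construction forces a common axis but keeps residual size", {
  x <- simulateOntogeny(n_species = 5, n_per_species = 25,
                        perturbation_deg = 12, residual_sd = 0.03,
                        missing_fraction = 0, seed = 31)
  mats <- alloaxis:::.speciesMatrices(logTransform(x))
  vc <- vectorCoefficients(commonAllometricVector(mats))
  conf <- conformingDataset(mats, vc)
  for (s in names(mats)) {
    # per-species PC1 of the conforming data sits on the common axis up
    # to the finite-sample score/residual cross-covariance
    expect_lt(angleBetween(alloaxis:::.pc1(conf[[s]])$vector, vc), 0.5)
    # species means survive
    expect_equal(colMeans(conf[[s]]), colMeans(mats[[s]]),
                 tolerance = 1e-12)
    # residual norms per specimen survive (off-axis noise magnitude kept)
    Xc <- sweep(mats[[s]], 2, colMeans(mats[[s]]), "-")
    vs <- alloaxis:::.pc1(mats[[s]])$vector
    rn0 <- sqrt(rowSums((Xc - (Xc %*% vs) %*% t(vs))^2))
    Yc <- sweep(conf[[s]], 2, colMeans(conf[[s]]), "-")
    rn1 <- sqrt(rowSums((Yc - (Yc %*% vc) %*% t(vc))^2))
    expect_equal(rn1, rn0, tolerance = 1e-8)
  }
})

test_that("the shared-allometry null flags only truly deviant species", {
  # data exactly rank-1 on one axis: all observed angles zero, none exceed
  u <- c(2, 2, 1, 1, 1, 1); u <- u / sqrt(sum(u^2))
  s <- seq(0, 3, length.out = 20)
  mats <- list(a = outer(s, u), b = outer(s + 0.5, u), c = outer(2 * s, u))
  mats <- lapply(mats, function(M) { colnames(M) <- fore6; M })
  res <- sharedAllometryNull(mats, B = 200, seed = 5)
  expect_equal(unname(angleMatrix(res)), matrix(0, 3, 3), tolerance = 1e-8)
  expect_false(any(res@pairs$exceeds_null))
  # one species rotated 25 degrees at low noise: its pairs are flagged
  set.seed(6)
  xs <- simulateOntogeny(n_species = 4, n_per_species = 30,
                         perturbation_deg = 0, residual_sd = 0.02,
                         missing_fraction = 0, seed = 41)
  mats2 <- alloaxis:::.speciesMatrices(logTransform(xs))
  v0 <- S4Vectors::metadata(xs)$true_common_vector
  vrot <- alloaxis:::.tiltVector(v0, 25)
  sc <- seq(0, 5, length.out = 30)
  M4 <- outer(sc, vrot) + matrix(rnorm(180, sd = 0.02), 30, 6) +
    matrix(rep(log(0.5), 180), 30, 6)
  colnames(M4) <- fore6
  mats2$sp04 <- M4
  res2 <- sharedAllometryNull(mats2, B = 300, seed = 7)
  flagged <- res2@pairs$exceeds_null
  touches4 <- res2@pairs$label1 == "sp04" | res2@pairs$label2 == "sp04"
  expect_true(all(flagged[touches4]))
  expect_false(any(flagged[!touches4]))
})

test_that("allometric space ordination separates deviant growth patterns", {
  set.seed(8)
  base <- c(2, 2, 1, 1, 1, 1); base <- base / sqrt(sum(base^2))
  mk <- function(v) {
    v <- v / sqrt(sum(v^2))
    names(v) <- fore6
    v
  }
  vecs <- lapply(1:6, function(i) mk(base + rnorm(6, sd = 0.01)))
  names(vecs) <- paste0("sp", 1:6)
  # identical vectors: all scores at the origin
  same <- rep(vecs[1], 3); names(same) <- paste0("v", 1:3)
  sp0 <- allometricSpace(same)
  expect_lt(max(abs(sp0@scores)), 1e-12)
  # an outlier species takes the extreme PC1 score
  vecs$outlier <- mk(base + c(0.5, -0.4, 0.3, 0, 0, 0))
  sp1 <- allometricSpace(vecs)
  expect_identical(rownames(sp1@scores)[which.max(abs(sp1@scores[, 1]))],
                   "outlier")
  # scores reproduce pairwise distances from a direct eigen oracle
  V <- do.call(rbind, vecs)
  D0 <- as.matrix(dist(sweep(V, 2, colMeans(V))))
  D1 <- as.matrix(dist(sp1@scores))
  expect_equal(unname(D1), unname(D0), tolerance = 1e-10)
  expect_error(allometricSpace(vecs[1:2]), "at least three")
})
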