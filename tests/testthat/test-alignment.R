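test_that("the aligning rotation is orthogonal and exact", {
  set.seed(44)
  for (r in 1:10) {
    u <- rnorm(6); u <- u / sqrt(sum(u^2))
    v <- rnorm(6); v <- v / sqrt(sum(v^2))
    R <- rotationAligning(u, v)
    expect_lt(max(abs(t(R) %*% R - diag(6))), 1e-12)
    expect_lt(max(abs(R %*% u - v)), 1e-12)
    # identity off the plane: vectors orthogonal to both are untouched
    w <- rnorm(6)
    w <- w - sum(w * u) * u
    vp <- v - sum(v * u) * u
    w <- w - sum(w * vp) / sum(vp * vp) * vp
    expect_lt(max(abs(R %*% w - w)), 1e-10)
  }
  expect_equal(rotationAligning(c(1, 0), c(1, 0)), diag(2))
  expect_error(rotationAligning(c(1, 0), c(-1, 0)), "antipodal")
})

test_that("angles between limb-mismatched vectors are refused", {
  v6 <- setNames(rep(1 / sqrt(6), 6), fore6)
  v7 <- setNames(rep(1 / sqrt(7), 7), hind7)
  expect_error(ontoPhyloAngle(v6, v7), "same limb")
  expect_equal(ontoPhyloAngle(v6, v6), 0)
  e1 <- c(1, 0, 0, 0, 0, 0); e2 <- c(0, 1, 0, 0, 0, 0)
  expect_equal(ontoPhyloAngle(e1, e2), 90)
})

test_that("axes estimated from onto and evo data built on one axis nearly coincide", {
  w <- alignedWorld(seed = 51)
  cp <- commonAllometricVector(w$ontoLog)
  pp <- phyloPCA(w$means, w$tree)
  expect_lt(ontoPhyloAngle(cp, axisVector(pp, 1)), 3)
})

test_that("the aligned null accepts truly aligned data and rejects a 25-degree offset", {
  w <- alignedWorld(seed = 52)
  res <- alignedNull(w$ontoLog, w$means, w$tree, B = 300, seed = 53)
  expect_s4_class(res, "AlignmentTest")
  expect_true(res@aligned)
  expect_identical(res@aligned, res@thetaObs <= res@ci95Upper)
  w2 <- alignedWorld(offset_deg = 25, evo_noise = 0.02, seed = 54)
  res2 <- alignedNull(w2$ontoLog, w2$means, w2$tree, B = 300, seed = 55)
  expect_false(res2@aligned)
  expect_gt(res2@thetaObs, 15)
  expect_error(alignedNull(w$ontoLog, w$means, w$tree, B = 50), "100")
})

test_that("species exclusion removes a species from the ontogenetic side", {
  w <- alignedWorld(n_species = 6, seed = 56)
  res <- alignedNull(w$ontoLog, w$means, w$tree, exclude = "sp01",
                     B = 150, seed = 57)
  expect_true(res@aligned)
  expect_error(alignedNull(w$ontoLog, w$means, w$tree,
                           exclude = sprintf("sp%02d", 1:5), B = 150),
               "fewer than two")
})

test_that("degenerate noise-free data give a zero angle and a degenerate null", {
  u <- c(2, 2, 1, 1, 1, 1); u <- u / sqrt(sum(u^2))
  s <- seq(0, 3, length.out = 20)
  mats <- lapply(1:3, function(i) {
    M <- outer(s + i / 2, u); colnames(M) <- fore6; M
  })
  onto <- do.call(rbind, mats)
  x <- LimbMeasurements(exp(onto),
                        specimen_id = sprintf("i%02d", 1:60),
                        species = rep(c("a", "b", "c"), each = 20),
                        life_stage = "embryo", size_proxy = rep(exp(s), 3))
  tr <- simulateTree(10, seed = 58)
  means <- outer(seq(0.2, 2, length.out = 10), u)
  dimnames(means) <- list(tr$tip.label, fore6)
  # rank-1 inputs make most eigenvalues exactly degenerate; the PCA warns
  res <- suppressWarnings(
    alignedNull(logTransform(x), means, tr, B = 150, seed = 59))
  expect_lt(res@thetaObs, 1e-6)
  expect_lt(max(res@nullAngles), 1e-4)
  expect_true(res@aligned)
})

test_that("the null angle distribution widens with residual noise", {
  med <- vapply(c(0.02, 0.1, 0.3), function(sdv) {
    v <- c(1.25, 1.25, 1, 1, 1, 1); v <- v / sqrt(sum(v^2))
    onto <- simulateOntogeny(n_species = 8, n_per_species = 20,
                             common_vector = v, perturbation_deg = 0,
                             residual_sd = sdv, missing_fraction = 0,
                             seed = 61)
    tr <- simulateTree(30, seed = 62)
    means <- simulateEvolution(tr, rep(log(10), 6),
                               rank1Covariance(v, 0.4, 0.99), seed = 63)
    res <- alignedNull(logTransform(onto), means, tr, B = 300, seed = 64)
    median(res@nullAngles)
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("hatchling and adult evolutionary axes are compared on one tree", {
  tr <- simulateTree(20, seed = 65)
  v <- c(2, 2, 1, 1, 1, 1); v <- v / sqrt(sum(v^2))
  adult <- simulateEvolution(tr, rep(log(20), 6),
                             rank1Covariance(v, 0.4, 0.95), seed = 66)
  A <- measurementMatrix(adult); rownames(A) <- speciesOf(adult)
  # identical tables: zero angle, trivially aligned
  res0 <- hatchlingVsAdult(A, A, tr, B = 150, seed = 67)
  expect_equal(res0@thetaObs, 0, tolerance = 1e-10)
  expect_true(res0@aligned)
  # adult = hatchling + moderate i.i.d. noise: aligned
  set.seed(68)
  H <- A + matrix(rnorm(length(A), sd = 0.02), nrow(A), ncol(A))
  rownames(H) <- rownames(A)
  res1 <- hatchlingVsAdult(H, A, tr, B = 200, seed = 69)
  expect_true(res1@aligned)
  # hatchling axis rotated 30 degrees: misaligned
  set.seed(70)
  vrot <- alloaxis:::.tiltVector(v, 30)
  Q <- rotationAligning(v, vrot)
  fit <- phyloPCA(A, tr)
  dev <- fit@scores %*% t(fit@eigenvectors)
  Hrot <- dev %*% t(Q) + matrix(fit@mean, nrow(A), 6, byrow = TRUE) +
    matrix(rnorm(length(A), sd = 0.005), nrow(A), ncol(A))
  dimnames(Hrot) <- dimnames(A)
  res2 <- hatchlingVsAdult(Hrot, A, tr, B = 200, seed = 71)
  expect_false(res2@aligned)
  expect_error(hatchlingVsAdult(H[1:10, ], A, tr), "species sets differ")
})
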