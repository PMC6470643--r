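test_that("PCA retains the minimal components reaching the variance rule", {
  set.seed(71)
  # rank-1: two identical copies of one feature
  f <- rnorm(30)
  red <- pcaReduce(cbind(f, f), scale = FALSE)
  expect_identical(red$nComponents, 1L)
  expect_equal(sum(red$explained[1]), 1.0, tolerance = 1e-12)

  # isotropic 6-d Gaussian: five of six equal-variance components are needed
  # to reach 70% (5/6 ~ 0.83 >= 0.70 > 4/6)
  X <- matrix(rnorm(10000 * 6), ncol = 6)
  expect_identical(pcaReduce(X, 0.70)$nComponents, 5L)

  # constant view errors
  expect_error(pcaReduce(matrix(1, 10, 3)), "constant")
})

test_that("PCA reconstruction error is non-increasing in component count", {
  set.seed(72)
  X <- matrix(rnorm(40 * 6), ncol = 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  Xc <- scale(X, scale = FALSE)
  pc <- prcomp(Xc)
  errs <- vapply(1:6, function(k) {
    approxX <- pc$x[, 1:k, drop = FALSE] %*% t(pc$rotation[, 1:k, drop = FALSE])
    sum((Xc - approxX)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("CCA fusion matches the generalized-eigenvalue oracle", {
  set.seed(73)
  for (i in 1:25) {
    n <- 50
    pa <- sample(2:3, 1); pb <- sample(2:3, 1)
    A <- matrix(rnorm(n * pa), n)
    B <- 0.5 * A[, seq_len(min(pa, pb)), drop = FALSE][, rep(1, pb)] +
      matrix(rnorm(n * pb), n)
    fu <- ccaFuse(A, B)
    expect_equal(canonicalCorrelations(fu), ccaEigenOracle(A, B),
                 tolerance = 1e-8)
  }
})

test_that("identical views give unit correlations; independent views near zero", {
  set.seed(74)
  A <- matrix(rnorm(30 * 2), 30)
  expect_equal(canonicalCorrelations(ccaFuse(A, A)), c(1, 1),
               tolerance = 1e-9)

  big <- matrix(rnorm(10000 * 2), ncol = 2)
  noise <- matrix(rnorm(10000 * 2), ncol = 2)
  expect_true(all(canonicalCorrelations(ccaFuse(big, noise)) < 0.05))
})

test_that("the fused matrix always has 2 min(rank A, rank B) columns", {
  set.seed(75)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    pa <- sample(1:4, 1); pb <- sample(1:4, 1)
    A <- matrix(rnorm(n * pa), n)
    B <- matrix(rnorm(n * pb), n)
    fu <- ccaFuse(A, B)
    expect_identical(ncol(fusedFeatures(fu)), 2L * min(pa, pb))
  }
  # rank-deficient view: duplicated column does not add to r
  A <- matrix(rnorm(20 * 2), 20)
  Adup <- cbind(A, A[, 1])
  B <- matrix(rnorm(20 * 3), 20)
  expect_length(canonicalCorrelations(ccaFuse(Adup, B)), 2L)
})

test_that("canonical projections have the stated correlation structure", {
  set.seed(76)
  A <- matrix(rnorm(200 * 3), 200)
  B <- A %*% matrix(rnorm(9), 3) + 0.5 * matrix(rnorm(200 * 3), 200)
  fu <- ccaFuse(A, B)
  rho <- canonicalCorrelations(fu)
  cr <- cor(fu@X, fu@Y)
  # corr(X_i, Y_j) ~ rho_i * delta_ij
  expect_equal(diag(cr), rho, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(cr[upper.tri(cr)]) < 1e-6))
  expect_true(all(abs(cr[lower.tri(cr)]) < 1e-6))
})

test_that("correlations are invariant to invertible transforms of a view", {
  set.seed(77)
  A <- matrix(rnorm(40 * 2), 40)
  B <- matrix(rnorm(40 * 2), 40)
  rho <- canonicalCorrelations(ccaFuse(A, B))
  for (i in 1:5) {
    M <- matrix(rnorm(4), 2)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(4), 2)
    expect_equal(canonicalCorrelations(ccaFuse(A %*% M, B)), rho,
                 tolerance = 1e-8)
  }
})

test_that("CCA input validation", {
  A <- matrix(rnorm(20), 10)
  expect_error(ccaFuse(A, matrix(rnorm(22), 11)), "subject counts differ")
  expect_error(ccaFuse(matrix(0, 10, 2), A), "zero-rank")
  expect_error(ccaFuse(A[1, , drop = FALSE], A[1, , drop = FALSE]),
               "at least 2")
})

test_that("feature-set assembly reproduces the four-set design", {
  set.seed(78)
  n <- 24
  # every electrode loads on two latent factors (plus small noise), so the
  # 70% rule keeps exactly 2 PCs per view even after z-scoring
  latent <- matrix(rnorm(n * 2), n)
  # balanced orthogonal loadings: each factor carries ~50% of the variance,
  # so one PC is never enough and two always are
  L <- rbind(rep(2, 6), c(2, -2, 2, -2, 2, -2))
  rpsd <- latent %*% L + 0.2 * matrix(rnorm(n * 6), n)
  pe <- latent[, 2:1] %*% L + 0.2 * matrix(rnorm(n * 6), n)
  sets <- assembleFeatureSets(rpsd, pe)
  expect_identical(ncol(sets$set1), 2L)
  expect_identical(ncol(sets$set2), 2L)
  expect_identical(ncol(sets$set3), 4L)
  expect_identical(ncol(sets$set4), 4L)
  expect_identical(sets$set3, cbind(sets$set1, sets$set2))

  expect_error(
    assembleFeatureSets(rpsd[1, , drop = FALSE], pe[1, , drop = FALSE]),
    "at least 2"
  )
})

test_that("permuting subjects permutes all four sets identically", {
  set.seed(79)
  n <- 20
  latent <- matrix(rnorm(n * 2), n)
  rpsd <- cbind(latent * 2, 0.3 * matrix(rnorm(n * 2), n))
  pe <- cbind(latent %*% matrix(c(1, .3, .2, 1), 2),
              0.3 * matrix(rnorm(n * 2), n))
  sets <- assembleFeatureSets(rpsd, pe)
  perm <- sample(n)
  setsP <- assembleFeatureSets(rpsd[perm, ], pe[perm, ])
  for (nm in c("set1", "set2", "set3", "set4")) {
    expect_equal(setsP[[nm]], sets[[nm]][perm, ], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})
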