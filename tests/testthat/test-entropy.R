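test_that("permutation entropy matches closed-form boundary cases", {
  # a strictly monotone series visits a single ordinal pattern
  expect_identical(permutationEntropy(1:100, m = 3, tau = 1), 0)
  expect_identical(permutationEntropy(seq(5, 1, length.out = 50), m = 3), 0)

  # cyclic sequence (1,2,5,4,3,6) realises all 6 patterns of m = 3 once per
  # period, so a whole number of periods gives the maximal entropy log(6)
  base <- c(1, 2, 5, 4, 3, 6)
  x <- rep(base, 41)[1:(6 * 40 + 2)]
  expect_equal(permutationEntropy(x, m = 3), log(6), tolerance = 1e-14)
  expect_equal(permutationEntropy(x, m = 3, normalize = TRUE), 1,
               tolerance = 1e-14)

  # the worked example: enumerate the 5 triplets by hand via the oracle
  v <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutationEntropy(v, m = 3, tau = 1),
               bruteForcePE(v, m = 3, tau = 1), tolerance = 1e-15)
})

test_that("fast implementation equals the brute-force oracle on random input", {
  set.seed(101)
  for (m in 3:5) {
    for (tau in 1:3) {
      for (rep in 1:8) {
        n <- sample(50:300, 1)
        x <- rnorm(n)
        expect_equal(
          permutationEntropy(x, m = m, tau = tau),
          bruteForcePE(x, m = m, tau = tau),
          tolerance = 1e-12
        )
      }
    }
  }
  # discretised data with many ties
  for (rep in 1:10) {
    x <- sample(1:4, 150, replace = TRUE)
    expect_equal(
      permutationEntropy(x, m = 3, tau = 1),
      bruteForcePE(x, m = 3, tau = 1),
      tolerance = 1e-12
    )
  }
})

test_that("PE is invariant under strictly monotone transforms and bounded", {
  set.seed(7)
  x <- rnorm(500)
  h <- permutationEntropy(x, m = 4)
  expect_identical(permutationEntropy(exp(x), m = 4), h)
  expect_identical(permutationEntropy(3 * x + 1, m = 4), h)
  expect_gte(h, 0)
  expect_lte(h, log(factorial(4)))
  expect_lte(permutationEntropy(x, m = 4, normalize = TRUE), 1)
  # bits and nats differ by the log(2) factor only
  expect_equal(permutationEntropy(x, m = 3, base = 2) * log(2),
               permutationEntropy(x, m = 3), tolerance = 1e-12)
})

test_that("tie handling is deterministic and matches the stable-sort oracle", {
  x <- c(2, 2, 1, 3, 2, 2, 1, 1, 3, 3, 2)
  expect_equal(permutationEntropy(x, m = 3), bruteForcePE(x, m = 3),
               tolerance = 1e-14)
  # repeated evaluation is bit-identical; the jitter option also returns a
  # deterministic value for a fixed seed
  expect_identical(permutationEntropy(x, m = 3), permutationEntropy(x, m = 3))
  j1 <- permutationEntropy(x, m = 3, tieBreak = "jitter", jitterSeed = 4)
  j2 <- permutationEntropy(x, m = 3, tieBreak = "jitter", jitterSeed = 4)
  expect_identical(j1, j2)
})

test_that("input validation rejects short series and bad orders", {
  expect_error(permutationEntropy(1:3, m = 4), "too short")
  expect_error(permutationEntropy(1:100, m = 1), "'m' must be")
  expect_error(permutationEntropy(1:100, m = 12), "'m' must be")
  expect_error(permutationEntropy(1:100, m = 3, tau = 0), "'tau'")
})

test_that("time-varying PE splits windows correctly and tracks change points", {
  set.seed(5)
  x <- rnorm(1000)
  # degenerate single window equals plain PE of the signal
  tv1 <- timeVaryingPE(x, m = 3, nWindows = 1)
  expect_equal(nrow(tv1), 1L)
  expect_equal(tv1$pe, permutationEntropy(x, m = 3))

  # stationary noise: window PEs scatter within Monte-Carlo range of the
  # full-signal value
  tv <- timeVaryingPE(x, m = 3, windowSamples = 200)
  expect_equal(nrow(tv), 5L)
  expect_equal(tv$start, c(1, 201, 401, 601, 801))
  mc <- replicate(200, permutationEntropy(rnorm(200), m = 3))
  expect_true(all(abs(tv$pe - permutationEntropy(x, m = 3)) <= 3 * sd(mc)))

  # near-periodic -> white noise switch: second-half PE strictly larger
  t <- seq_len(500)
  xa <- sin(2 * pi * t / 25)
  xb <- rnorm(500)
  tvc <- timeVaryingPE(c(xa, xb), m = 4, windowSamples = 100)
  expect_gt(mean(tvc$pe[6:10]), mean(tvc$pe[1:5]))

  expect_error(timeVaryingPE(x, m = 4, windowSamples = 3), "too short")
  expect_error(timeVaryingPE(x, m = 4), "exactly one")
})

test_that("per-band PE behaves at the band extremes", {
  set.seed(9)
  fs <- 250
  rec <- EEGRecording(matrix(rnorm(2 * fs * 4), 2), fs = fs, label = 0L)
  eps <- segmentEpochs(rec, 4)

  # all-pass band reproduces the unfiltered PE closely
  allpass <- bandpassFilter(eps, fLow = 0.5, fHigh = fs / 2 * 0.999)
  peRaw <- complexityFeatures(eps, m = 3)
  peAll <- complexityFeatures(allpass, m = 3)
  expect_equal(peAll$pe, peRaw$pe, tolerance = 1e-3)

  # delta-limited noise pushed through gamma2: residual band power is near
  # zero but PE must still return a finite value
  slow <- bandpassFilter(eps, band = "delta")
  hi <- bandpassFilter(initialize(slow, band = NA_character_), band = "gamma2")
  peHi <- complexityFeatures(hi, m = 3)
  expect_true(all(is.finite(peHi$pe)))

  # banded table layout: 6 bands x 1 epoch x 2 channels
  pb <- pePerBand(eps, m = 3)
  expect_setequal(unique(pb$band), eegBands()$band)
  expect_equal(nrow(pb), 12L)
})
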