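test_that("length-2 design recovers the constraint-forced Haar autocorrelation", {
  sol <- minBandwidthAutocorrelation(2, 1)
  expect_equal(sol$r, c(1, 0.5), tolerance = 1e-10)
  expect_equal(sol$b_sq, pi^2 / 3 - 2, tolerance = 1e-8)
})

test_that("the length-12 / 4-VM autocorrelation satisfies its invariants", {
  sol <- minBandwidthAutocorrelation(12, 4)
  r <- sol$r
  expect_equal(r[1], 1, tolerance = 1e-8)
  expect_true(all(abs(r[seq(3, 11, by = 2)]) < 1e-8))  # even lags 2,4,...,10
  w <- seq(0, pi, length.out = 5000)
  R <- r[1] + 2 * drop(cos(outer(w, 1:11)) %*% r[-1])
  expect_true(min(R) >= -1e-8)
})

test_that("the designed bandwidth beats Daubechies-6 and Symlet-6", {
  sol <- minBandwidthAutocorrelation(12, 4)
  expect_lt(sol$b_sq, rmsBandwidth(DB6_H)$b_sq)
  expect_lt(sol$b_sq, rmsBandwidth(SYM6_H)$b_sq)
})

test_that("infeasible vanishing-moment requests are rejected", {
  expect_error(minBandwidthAutocorrelation(4, 3), "infeasible")
  expect_error(minBandwidthAutocorrelation(11, 2), "even")
})

test_that("spectral factorization round-trips autocorrelations", {
  expect_equal(spectralFactorize(c(1, 0.5)), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  sol <- minBandwidthAutocorrelation(12, 4)
  h <- spectralFactorize(sol$r)
  expect_lt(max(abs(autocorrelation(h) - sol$r)), 1e-5)
  # strictly positive spectrum, L = 4: residual below 1e-6
  set.seed(4)
  h0 <- rnorm(4)
  r4 <- autocorrelation(h0) / sum(h0^2)
  h4 <- spectralFactorize(r4)
  expect_lt(max(abs(autocorrelation(h4) - r4)), 1e-6)
  expect_gt(sum(h4), 0)
})

test_that("invalid spectra are rejected with a projection hint", {
  expect_error(spectralFactorize(c(1, 0.9)), "nonnegative cone")
})

test_that("the full design composes into a valid filter bank", {
  fb <- omsbmBank()
  expect_true(validObject(fb))
  expect_identical(length(lowpass(fb)), 12L)
  expect_equal(sum(lowpass(fb)), sqrt(2), tolerance = 1e-6)
  expect_equal(sum(highpass(fb)), 0, tolerance = 1e-6)
  expect_identical(countVanishingMoments(highpass(fb)), 4L)
  # highpass moment sums below 1e-6 for m = 0..3
  n <- 0:11
  for (m in 0:3) expect_lt(abs(sum(n^m * highpass(fb))), 1e-6)
})

test_that("the Haar bank reconstructs short signals essentially exactly", {
  fb <- designMinBandwidthFilter(2, 1, 1)
  expect_equal(lowpass(fb), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_lt(max(abs(idwt(dwt(x, fb), fb) - x)), 1e-10)
})

test_that("closed-form bandwidth agrees with numerical quadrature", {
  haar <- rep(1 / sqrt(2), 2)
  expect_equal(rmsBandwidth(haar)$b_sq, pi^2 / 3 - 2, tolerance = 1e-8)
  expect_equal(rmsBandwidth(haar)$b_sq, quadratureBandwidth(haar),
               tolerance = 1e-6)
  expect_equal(rmsBandwidth(1)$b_sq, pi^2 / 3, tolerance = 1e-12)
  for (h in list(DB6_H, lowpass(omsbmBank()))) {
    expect_equal(rmsBandwidth(h)$b_sq, quadratureBandwidth(h),
                 tolerance = 1e-6)
  }
})

test_that("vanishing moments are counted correctly on reference filters", {
  expect_identical(countVanishingMoments(cqfHighpass(rep(1 / sqrt(2), 2))), 1L)
  expect_identical(countVanishingMoments(cqfHighpass(DB2_H)), 2L)
  expect_identical(countVanishingMoments(cqfHighpass(DB6_H)), 6L)
  expect_error(countVanishingMoments(numeric(0)), "non-empty")
  expect_error(countVanishingMoments(c(1, -1), tol = 0), "positive")
})

test_that("filter banks survive text serialization", {
  fb <- omsbmBank()
  path <- withr::local_tempfile(fileext = ".txt")
  writeFilterBank(fb, path)
  fb2 <- readFilterBank(path)
  expect_equal(lowpass(fb2), lowpass(fb), tolerance = 1e-12)
  expect_identical(decompositionLevels(fb2), 5L)
  expect_identical(fb2@vanishingMoments, 4L)
})
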