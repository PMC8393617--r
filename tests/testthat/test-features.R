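test_that("wavelet entropy follows the magnitude-sum definition", {
  expect_equal(waveletEntropy(1), 0)
  expect_equal(waveletEntropy(c(0, 0, 0)), 0)
  expect_equal(waveletEntropy(c(0.5, 0.5)), log(2))
  # permutation invariance and sign invariance
  set.seed(41)
  cc <- rnorm(32)
  expect_equal(waveletEntropy(cc), waveletEntropy(sample(cc)))
  expect_equal(waveletEntropy(cc), waveletEntropy(-cc))
  # normalized mode is the Shannon entropy of |c|/sum|c|
  p <- abs(cc) / sum(abs(cc))
  expect_equal(waveletEntropy(cc, normalize = TRUE), -sum(p * log(p)))
})

test_that("Hjorth parameters match their sampling-theory values", {
  expect_equal(hjorthActivity(rep(4, 10)), 0)
  expect_error(hjorthMobility(rep(4, 10)), "constant")
  expect_error(hjorthComplexity(rep(4, 10)), "constant")
  set.seed(42)
  x <- rnorm(1e5)
  expect_equal(hjorthMobility(x), sqrt(2), tolerance = 0.02)
  # densely sampled tone: mobility ~ 2 sin(pi f / fs), complexity ~ 1
  fs <- 512; f <- 10
  s <- sin(2 * pi * f * (0:(20 * fs - 1)) / fs)
  expect_equal(hjorthMobility(s), 2 * sin(pi * f / fs), tolerance = 1e-3)
  expect_equal(hjorthComplexity(s), 1, tolerance = 1e-2)
  expect_equal(hjorthActivity(s), 0.5, tolerance = 1e-3)
})

test_that("epoch extraction yields the named 24/48-dimensional vectors", {
  fb <- omsbmBank()
  set.seed(43)
  ep <- matrix(rnorm(256), 128, 2,
               dimnames = list(NULL, c("C4-A1", "F4-C4")))
  v <- extractEpochFeatures(ep, fb)
  expect_length(v, 48L)
  expect_identical(names(v)[1:4],
                   c("C4-A1.D1.entropy", "C4-A1.D1.activity",
                     "C4-A1.D1.mobility", "C4-A1.D1.complexity"))
  expect_identical(names(v)[45:48],
                   c("F4-C4.A5.entropy", "F4-C4.A5.activity",
                     "F4-C4.A5.mobility", "F4-C4.A5.complexity"))
  expect_length(extractEpochFeatures(ep[, 1], fb), 24L)
  # identical epochs give identical vectors
  expect_identical(v, extractEpochFeatures(ep, fb))
  # an all-zero epoch degenerates to zeros with warnings (one per subband)
  w <- capture_warnings(v0 <- extractEpochFeatures(matrix(0, 128, 1), fb))
  expect_true(all(grepl("degenerate", w)))
  expect_true(all(v0 == 0))
})

test_that("feature sets assemble with labels and survive accessors", {
  es <- simpleEpochSet(n = 12)
  fs <- extractFeatures(es, omsbmBank())
  expect_s4_class(fs, "CAPFeatureSet")
  expect_identical(dim(featureMatrix(fs)), c(12L, 48L))
  expect_identical(as.character(phaseLabels(fs)),
                   rep(c("A", "B"), length.out = 12))
})

test_that("Kruskal-Wallis ranking matches the hand-evaluated statistic", {
  # groups {1,2,3} vs {4,5,6}: ranks 1..6, H = 12/(6*7) * (36/3 + 225/3) - 21
  mat <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
                dimnames = list(NULL, "f"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(mat)),
    colData = S4Vectors::DataFrame(
      phase = factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))))
  fsx <- new("CAPFeatureSet", se)
  rk <- rankFeatures(fsx)
  expect_equal(rk$H, 3.857, tolerance = 1e-3)
  expect_equal(rk$p_value, 0.0495, tolerance = 1e-3)
  # identical groups: H = 0, p = 1
  mat2 <- cbind(f1 = c(1, 2, 3, 1, 2, 3), f2 = c(1, 2, 3, 4, 5, 6))
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(mat2)),
    colData = S4Vectors::DataFrame(
      phase = factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))))
  rk2 <- rankFeatures(new("CAPFeatureSet", se2))
  expect_equal(rk2$H[1], 0, tolerance = 1e-10)
  expect_equal(rk2$p_value[1], 1, tolerance = 1e-10)
  expect_identical(sort(rk2$rank), 1:2)
  expect_identical(rk2$rank[2], 1L)          # more significant feature first
})

test_that("ranks are a permutation on wide feature sets", {
  es <- simpleEpochSet(n = 20)
  rk <- rankFeatures(extractFeatures(es, omsbmBank()))
  expect_identical(sort(rk$rank), 1:48)
  expect_true(all(diff(rk$p_value[order(rk$rank)]) >= -1e-12))
})

test_that("low-frequency activity separates synthetic phase A from B", {
  es <- simulateEpochSet(synthParams(nEpochs = 40, ampRatio = 5, seed = 44))
  ep <- preprocessEpochs(es)
  fs <- extractFeatures(ep, omsbmBank())
  mat <- featureMatrix(fs)
  lab <- phaseLabels(fs)
  for (feat in c("C4-A1.D5.activity", "C4-A1.A5.activity"))
    expect_gt(median(mat[lab == "A", feat]), median(mat[lab == "B", feat]))
})
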