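test_that("the generator is deterministic and shape-correct", {
  p <- synthParams(nEpochs = 5, seed = 61)
  e1 <- simulateEpochSet(p)
  e2 <- simulateEpochSet(p)
  expect_identical(e1@data, e2@data)
  expect_identical(dim(e1@data), c(10L, 1024L, 2L))
  expect_identical(as.vector(table(e1@labels)), c(5L, 5L))
  e3 <- simulateEpochSet(synthParams(nEpochs = 5, seed = 62))
  expect_false(identical(e1@data, e3@data))
  expect_error(synthParams(ampRatio = 0.5), "ampRatio")
})

deltaPower <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n^2
  fr <- (0:(n - 1)) * fs / n
  sum(sp[fr >= 0.5 & fr <= 4])
}

test_that("amp_ratio 1 gives overlapping class laws, 5 separates them", {
  es <- simulateEpochSet(synthParams(nEpochs = 500, ampRatio = 1, seed = 63))
  dp <- apply(es@data[, , 1], 1, deltaPower, fs = 512)
  ks <- suppressWarnings(ks.test(dp[es@labels == "A"], dp[es@labels == "B"]))
  expect_lt(unname(ks$statistic), 0.1)
  es5 <- simulateEpochSet(synthParams(nEpochs = 150, ampRatio = 5, seed = 64))
  dp5 <- apply(es5@data[, , 1], 1, deltaPower, fs = 512)
  expect_gt(mean(dp5[es5@labels == "A"]), 3 * mean(dp5[es5@labels == "B"]))
})

test_that("the background spectral slope is recovered within 0.3", {
  for (beta in c(0.5, 1, 1.5)) {
    es <- simulateEpochSet(synthParams(nEpochs = 60, ampRatio = 1,
                                       backgroundExponent = beta, seed = 65))
    n <- dim(es@data)[2]
    fr <- (0:(n - 1)) * 512 / n
    keep <- fr >= 1 & fr <= 30
    psd <- rowMeans(apply(es@data[, , 1], 1, function(x) Mod(fft(x))^2))[keep]
    fit <- lm(log(psd) ~ log(fr[keep]))
    expect_equal(unname(-coef(fit)[2]), beta, tolerance = 0.3)
  }
})

test_that("annotated recordings recover their layout through the CAP rules", {
  lay <- data.frame(onset = c(10, 50, 90), duration = c(10, 10, 10))
  r <- simulateRecording(synthParams(nEpochs = 1, seed = 66), lay)
  expect_length(r$channels, 2L)
  expect_equal(r$annotations$onset, lay$onset)
  seqs <- buildCapSequences(mergePhaseA(r$annotations))
  expect_length(seqs, 1L)
  expect_equal(seqs[[1]]$n_A, 3L)
  # bookkeeping identity: CAP time of the layout equals the computed one
  cp <- computeCapParameters(seqs, nremTime = 10)
  expect_equal(cp$cap_time * 60, 90)
  # two A phases only: no sequence
  lay2 <- data.frame(onset = c(10, 50), duration = c(10, 10))
  r2 <- simulateRecording(synthParams(nEpochs = 1, seed = 66), lay2)
  expect_length(buildCapSequences(mergePhaseA(r2$annotations)), 0L)
  expect_error(simulateRecording(synthParams(), data.frame(onset = 0, duration = 90)),
               "\\[2, 60\\]")
})

test_that("two channels share background but are not duplicated", {
  es <- simulateEpochSet(synthParams(nEpochs = 50, ampRatio = 1, seed = 67))
  cors <- vapply(seq_len(dim(es@data)[1]), function(i)
    cor(es@data[i, , 1], es@data[i, , 2]), 0.0)
  expect_gt(mean(cors), 0.3)
  expect_lt(mean(cors), 0.7)
})
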