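tsv <- function(...) paste(..., sep = "\t")

test_that("simple TSV annotations parse, sort and validate", {
  ev <- parseAnnotations(c(tsv("30.0", "5.0", "A2"), tsv("10.0", "8.0", "A1")))
  expect_equal(ev$onset, c(10, 30))
  expect_equal(ev$duration, c(8, 5))
  expect_equal(ev$label, c("A1", "A2"))
  expect_warning(parseAnnotations(c(tsv("1", "2", "A1"), tsv("5", "2", "XX"))),
                 "unknown label")
  expect_error(parseAnnotations("garbage line"), "line 1")
  expect_error(parseAnnotations(c(tsv("0", "10", "A1"), tsv("5", "10", "A2"))),
               "overlapping")
})

test_that("the PhysioNet event dialect parses stages and MCAP events", {
  lines <- c("Sleep Stage\tPosition\tTime [hh:mm:ss]\tEvent\tDuration[s]\tLocation",
             "S2\tSupine\t23:59:50\tSLEEP-S2\t30\tC4-A1",
             "S2\tSupine\t00:00:10\tMCAP-A1\t8\tC4-A1",
             "S2\tSupine\t00:00:40\tMCAP-A3\t5\tC4-A1")
  ev <- parseAnnotations(lines, dialect = "physionet-cap")
  expect_equal(ev$label, c("NREM2", "A1", "A3"))
  expect_equal(ev$onset, c(0, 20, 50))       # wraps past midnight
  expect_equal(ev$duration, c(30, 8, 5))
})

test_that("the shipped synthetic event-list example parses end to end", {
  f <- system.file("extdata", "synthetic-cap-events.txt", package = "capdet")
  ev <- parseAnnotations(f, dialect = "physionet-cap")
  expect_equal(sum(ev$label %in% c("A1", "A2", "A3")), 3L)
  expect_equal(sum(ev$label == "REM"), 1L)
  expect_equal(min(ev$onset), 0)           # midnight wrap handled
  expect_true(all(diff(ev$onset) >= 0))
})

test_that("phase-A merging follows the strict 2 s rule and cascades", {
  A <- function(on, dur) data.frame(onset = on, duration = dur, label = "A1")
  m <- mergePhaseA(rbind(A(0, 5), A(6.5, 3.5)))       # 1.5 s gap
  expect_equal(m$onset, 0); expect_equal(m$duration, 10)
  m2 <- mergePhaseA(rbind(A(0, 5), A(7, 3)))          # exactly 2 s gap
  expect_equal(nrow(m2), 2L)
  m3 <- mergePhaseA(rbind(A(0, 4), A(5, 3), A(9.5, 2.5)))
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$duration, 12)
  expect_identical(mergePhaseA(m3), m3)               # idempotent
})

test_that("CAP sequences require three A phases and break on long gaps", {
  A <- function(on, dur) data.frame(onset = on, duration = dur, label = "A")
  s1 <- buildCapSequences(rbind(A(0, 10), A(40, 10), A(80, 10)))
  expect_length(s1, 1L)
  expect_equal(s1[[1]]$n_A, 3L)
  expect_equal(s1[[1]]$start, 0); expect_equal(s1[[1]]$end, 90)
  expect_identical(s1[[1]]$events$label, c("A", "B", "A", "B", "A"))
  expect_length(buildCapSequences(rbind(A(0, 10), A(40, 10))), 0L)
  expect_length(buildCapSequences(rbind(A(0, 10), A(100, 10), A(140, 10))), 0L)
  # sequence phases satisfy the duration invariants
  for (s in s1) {
    expect_true(all(s$events$duration >= 2 & s$events$duration <= 60))
    expect_true(all(diff(s$events$onset) > 0))
  }
})

test_that("CAP parameters reproduce clinical rate arithmetic", {
  expect_equal(round(capRate(144.50, 350.83), 2), 0.41)
  expect_equal(round(capRate(221.00, 283.00), 2), 0.78)
  expect_equal(computeCapParameters(list(), 100)$cap_rate, 0)
  expect_error(capRate(400, 300), "exceeds")
  A <- function(on, dur) data.frame(onset = on, duration = dur, label = "A")
  seqs <- buildCapSequences(rbind(A(0, 10), A(40, 10), A(80, 10)))
  cp <- computeCapParameters(seqs, nremTime = 10)
  expect_equal(cp$cap_time, 1.5)             # 90 s
  expect_equal(cp$cap_rate, 0.15)
})

test_that("segmentation tiles labeled intervals and drops partial windows", {
  fs <- 64
  x <- eegTimeSeries(sin((0:(60 * fs - 1)) / 7), fs = fs, label = "C4-A1")
  ev <- data.frame(onset = 20, duration = 10, label = "A1")
  es <- labelAndSegment(x, ev, epochLen = 2)
  expect_equal(sum(es@labels == "A"), 5L)
  expect_equal(sum(es@labels == "B"), 25L)
  # 7 s A interval -> 3 epochs; 1.9 s B interval -> 0 epochs
  x2 <- eegTimeSeries(cos((0:(10 * fs - 1)) / 3), fs = fs, label = "C4-A1")
  ev2 <- data.frame(onset = 1.9, duration = 7, label = "A1")
  es2 <- labelAndSegment(x2, ev2, epochLen = 2)
  expect_equal(sum(es2@labels == "A"), 3L)   # floor(7 / 2)
  expect_equal(sum(es2@labels == "B"), 0L)   # 1.9 s and 1.1 s B: too short
  expect_error(labelAndSegment(x, ev, epochLen = 3), "1 or 2")
})

test_that("segmentation covers NREM within one epoch length and skips REM", {
  fs <- 64
  x <- eegTimeSeries(sin((0:(120 * fs - 1)) / 9), fs = fs, label = "C4-A1")
  ev <- data.frame(onset = c(0, 60, 10),  duration = c(60, 60, 8),
                   label = c("NREM2", "REM", "A1"))
  es <- labelAndSegment(x, ev, epochLen = 2)
  labeledTime <- length(es@labels) * es@epochLen
  expect_lte(abs(labeledTime - 60), 2 * es@epochLen)
  expect_equal(sum(es@labels == "A"), 4L)
})

test_that("class balancing undersamples deterministically", {
  es <- simpleEpochSet(n = 160)
  es@labels <- factor(rep(c("A", "B"), c(100, 60)), levels = c("A", "B"))
  b1 <- balanceClasses(es, seed = 5)
  expect_equal(as.vector(table(b1@labels)), c(60L, 60L))
  b2 <- balanceClasses(es, seed = 5)
  expect_identical(b1@data, b2@data)
  b3 <- balanceClasses(es, seed = 6)
  expect_false(identical(b1@data, b3@data))
  even <- simpleEpochSet(n = 10)
  expect_identical(balanceClasses(even, seed = 1), even)
  es@labels <- factor(rep("A", 160), levels = c("A", "B"))
  expect_error(balanceClasses(es), "both classes")
})
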