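blobs <- function(n = 200, sep = 4, seed = 51, p = 5) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2), levels = c("A", "B"))
  x <- matrix(rnorm(n * p), n, p)
  x[y == "A", 1] <- x[y == "A", 1] + sep
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

test_that("separable data is learned and permuted labels stay at chance", {
  b <- blobs(200)
  fit <- trainClassifier("bagged_trees", b$x, b$y, seed = 1)
  pr <- predictPhase(fit, b$x)
  expect_gte(mean(pr$label == b$y), 0.99)
  set.seed(52)
  yperm <- sample(b$y)
  m <- crossValidate("bagged_trees", b$x, yperm, k = 5, seed = 2)
  expect_gt(m@aca, 40); expect_lt(m@aca, 60)
})

test_that("training and prediction are deterministic given the seed", {
  b <- blobs(120, sep = 1.5)
  for (kind in c("bagged_trees", "boosted_trees", "knn")) {
    f1 <- trainClassifier(kind, b$x, b$y, seed = 7)
    f2 <- trainClassifier(kind, b$x, b$y, seed = 7)
    expect_identical(predictPhase(f1, b$x, seed = 3)$score,
                     predictPhase(f2, b$x, seed = 3)$score)
  }
  expect_error(trainClassifier("bagged_trees", b$x,
                               factor(rep("A", 120), levels = c("A", "B"))),
               "single-class")
})

test_that("every classifier family handles a separable problem", {
  b <- blobs(100, sep = 6)
  for (kind in c("bagged_trees", "boosted_trees", "svm_rbf", "knn",
                 "logistic", "fine_tree")) {
    m <- crossValidate(kind, b$x, b$y, k = 5, seed = 4)
    expect_gte(m@aca, 90)
  }
})

test_that("cross-validation generalizes to leave-one-out and input checks", {
  b <- blobs(20, sep = 8)
  m <- crossValidate("knn", b$x, b$y, k = 20, seed = 5,
                     params = list(k = 3))
  expect_equal(m@aca, 100)
  expect_error(crossValidate("knn", b$x, b$y, k = 30), "folds")
  expect_error(crossValidate("knn", b$x, b$y, k = 1), "at least 2")
})

test_that("fold assignment is invariant to row shuffling", {
  b <- blobs(100, sep = 2)
  ord <- withr::with_seed(53, sample(100))
  m1 <- crossValidate("fine_tree", b$x, b$y, k = 5, seed = 6)
  m2 <- crossValidate("fine_tree", b$x[ord, ], b$y[ord], k = 5, seed = 6)
  # same stratified seed mapping: pooled accuracy unchanged up to the
  # permutation of which samples land in which fold
  expect_s4_class(m2, "CAPMetrics")
  expect_lt(abs(m1@aca - m2@aca), 15)
})

test_that("confusion arithmetic reproduces published-style tables", {
  # identity and uniform matrices
  mId <- metricsFromConfusion(matrix(c(100, 0, 0, 100), 2, 2))
  expect_equal(mId@aca, 100); expect_equal(mId@kappa, 1)
  mU <- metricsFromConfusion(matrix(c(50, 50, 50, 50), 2, 2))
  expect_equal(mU@kappa, 0)
  # balanced binary identity: kappa = 2 ACA/100 - 1
  for (aa in c(60, 75.7, 83.3, 90)) {
    m <- metricsFromConfusion(matrix(c(aa, 100 - aa, 100 - aa, aa), 2, 2))
    expect_equal(m@kappa, 2 * m@aca / 100 - 1, tolerance = 1e-12)
  }
  expect_error(metricsFromConfusion(matrix(c(80, 10, 20, 80), 2, 2)),
               "sum to 100")
})

test_that("AUC follows the midrank Mann-Whitney formulation", {
  y <- factor(rep(c("A", "B"), each = 50), levels = c("A", "B"))
  expect_equal(aucFromScores(as.numeric(y == "A"), y), 1)
  expect_equal(aucFromScores(-as.numeric(y == "A"), y), 0)
  set.seed(54)
  s <- runif(100)
  a <- aucFromScores(s, y)
  expect_gt(a, 0.35); expect_lt(a, 0.65)
  # independent oracle: trapezoidal ROC area from pROC
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(pROC::roc(response = y, predictor = s,
                                              levels = c("B", "A"),
                                              direction = "<")))
  expect_equal(a, as.numeric(ref), tolerance = 1e-12)
  expect_error(aucFromScores(s, rep("A", 100)), "both classes")
})
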