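## Classifier family and the full metric suite. Defaults mirror common
## ensemble presets: bagging = 30 bootstrap trees with majority vote and
## mean-vote score; boosting = 30 depth-limited trees at learning rate 0.1;
## SVM = RBF kernel; KNN k = 10. All fits are deterministic given a seed.
## Metrics are computed on the pooled cross-validation confusion matrix
## (predicted in rows, actual in columns; percentages normalized per actual
## class), matching the layout of clinical CAP classification reports.

CLASSIFIER_KINDS <- c("bagged_trees", "boosted_trees", "svm_rbf", "knn",
                      "logistic", "fine_tree")

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Train a CAP phase classifier
#'
#' @param kind one of \code{"bagged_trees"} (bootstrap-aggregated decision
#'   trees), \code{"boosted_trees"} (gradient-boosted depth-limited trees),
#'   \code{"svm_rbf"}, \code{"knn"}, \code{"logistic"}, \code{"fine_tree"}.
#' @param x epochs-by-features numeric matrix, or a
#'   \linkS4class{CAPFeatureSet}.
#' @param y factor of phase labels (\code{"A"}/\code{"B"}); ignored when
#'   \code{x} is a \linkS4class{CAPFeatureSet}.
#' @param params named list overriding the defaults (\code{n_trees},
#'   \code{max_depth}, \code{learning_rate}, \code{k}, \code{cost},
#'   \code{gamma}).
#' @param seed RNG seed; fits are reproducible given the seed.
#' @return a \linkS4class{CAPModel}.
#' @export
trainClassifier <- function(kind, x, y = NULL, params = list(), seed = 1L) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  if (is(x, "CAPFeatureSet")) { y <- phaseLabels(x); x <- featureMatrix(x) }
  y <- factor(as.character(y), levels = c("A", "B"))
  if (anyNA(y)) stop('labels must be "A" or "B"')
  if (nlevels(droplevels(y)) < 2) stop("single-class input: cannot train")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- modifyList(list(n_trees = 30L, max_depth = 20L, learning_rate = 0.1,
                       k = 10L, cost = 1, gamma = 1 / ncol(x)), params)
  fit <- withSeed(seed, switch(kind,
    bagged_trees = randomForest::randomForest(
      x = x, y = y, ntree = p$n_trees, mtry = ncol(x), replace = TRUE),
    boosted_trees = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = p$learning_rate,
                    max_depth = min(p$max_depth, 6L), nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "A")),
      nrounds = p$n_trees, verbose = 0),
    svm_rbf = e1071::svm(x = x, y = y, kernel = "radial", cost = p$cost,
                         gamma = p$gamma, probability = TRUE),
    knn = list(train = x, cl = y, k = p$k),
    logistic = suppressWarnings(glm.fit(cbind(1, x), y == "A",
                                        family = binomial())),
    fine_tree = rpart::rpart(phase ~ ., data = data.frame(phase = y, x),
                             method = "class")))
  new("CAPModel", kind = kind, fit = fit, params = p,
      featureNames = colnames(x))
}

#' Predict phase labels and scores
#'
#' @param model a \linkS4class{CAPModel}.
#' @param x epochs-by-features matrix with the training columns.
#' @param seed RNG seed (used only by knn tie-breaking).
#' @return list with \code{label} (factor \code{A}/\code{B}) and
#'   \code{score} (probability of phase A).
#' @export
predictPhase <- function(model, x, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!identical(colnames(x), model@featureNames))
    x <- x[, model@featureNames, drop = FALSE]
  score <- switch(model@kind,
    bagged_trees = predict(model@fit, x, type = "prob")[, "A"],
    boosted_trees = predict(model@fit, xgboost::xgb.DMatrix(x)),
    svm_rbf = {
      pr <- attr(predict(model@fit, x, probability = TRUE), "probabilities")
      pr[, "A"]
    },
    knn = withSeed(seed, {
      kn <- class::knn(model@fit$train, x, model@fit$cl, k = model@fit$k,
                       prob = TRUE)
      pw <- attr(kn, "prob")
      ifelse(kn == "A", pw, 1 - pw)
    }),
    logistic = {
      cf <- model@fit$coefficients
      cf[is.na(cf)] <- 0                       # dropped collinear columns
      eta <- drop(cbind(1, x) %*% cf)
      1 / (1 + exp(-eta))
    },
    fine_tree = predict(model@fit, data.frame(x), type = "prob")[, "A"])
  score <- unname(score)
  list(label = factor(ifelse(score >= 0.5, "A", "B"), levels = c("A", "B")),
       score = score)
}

#' Stratified k-fold cross-validation
#'
#' Sample-wise stratified folds (default k = 10); per-fold predictions are
#' pooled into a single confusion matrix, metrics are computed on the
#' pooled matrix and scores are pooled for the AUC.
#'
#' @param kind classifier family, see \code{\link{trainClassifier}}.
#' @param x a \linkS4class{CAPFeatureSet}, or an epochs-by-features matrix
#'   with \code{y}.
#' @param y labels when \code{x} is a matrix.
#' @param k number of folds, \code{2 <= k <= n}.
#' @param seed RNG seed driving fold assignment and model fits.
#' @param params hyperparameters, see \code{\link{trainClassifier}}.
#' @return a \linkS4class{CAPMetrics}.
#' @export
crossValidate <- function(kind, x, y = NULL, k = 10L, seed = 1L,
                          params = list()) {
  if (is(x, "CAPFeatureSet")) { y <- phaseLabels(x); x <- featureMatrix(x) }
  y <- factor(as.character(y), levels = c("A", "B"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop(sprintf("n = %d is smaller than k = %d folds", n, k))
  folds <- withSeed(seed, {
    f <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  pred <- factor(rep("B", n), levels = c("A", "B"))
  score <- numeric(n)
  foldAcc <- numeric(k)
  for (fi in seq_len(k)) {
    te <- folds == fi
    fit <- trainClassifier(kind, x[!te, , drop = FALSE], y[!te],
                           params = params, seed = seed + fi)
    pr <- predictPhase(fit, x[te, , drop = FALSE], seed = seed + fi)
    pred[te] <- pr$label
    score[te] <- pr$score
    foldAcc[fi] <- mean(pr$label == y[te])
  }
  m <- metricsFromCounts(table(factor(pred, levels = c("A", "B")),
                               factor(y, levels = c("A", "B"))))
  m@auc <- aucFromScores(score, y)
  m@foldAccuracy <- foldAcc
  m
}

metricsFromCounts <- function(tab) {
  counts <- matrix(as.numeric(tab), 2, 2,
                   dimnames = list(predicted = c("A", "B"),
                                   actual = c("A", "B")))
  colSumsV <- colSums(counts)
  if (any(colSumsV == 0)) stop("a class is absent from the confusion matrix")
  colpct <- sweep(counts, 2, colSumsV, "/") * 100
  n <- sum(counts)
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSumsV) / n^2
  kappa <- (po - pe) / (1 - pe)
  rcl <- counts["A", "A"] / colSumsV["A"]
  pcn <- counts["A", "A"] / sum(counts["A", ])
  f1 <- if (pcn + rcl == 0) 0 else 2 * pcn * rcl / (pcn + rcl)
  new("CAPMetrics", confusion = counts, colpct = colpct,
      aca = unname(mean(diag(colpct))), pcn = unname(pcn),
      rcl = unname(rcl), f1 = unname(f1), kappa = unname(kappa))
}

#' Metrics from a column-percentage confusion matrix
#'
#' Reconstructs the metric suite from a published column-normalized
#' confusion matrix (predicted in rows, actual in columns, each column
#' summing to 100) and the class proportions. With balanced priors:
#' recall = colpct\[A,A\]/100, precision = colpct\[A,A\] /
#' (colpct\[A,A\] + colpct\[A,B\]), ACA = mean of the diagonal, and
#' kappa = (p_o - p_e)/(1 - p_e) with p_e = 1/2.
#'
#' @param colpct 2x2 matrix of column percentages (phase A column first).
#' @param priors actual-class proportions, summing to 1.
#' @return a \linkS4class{CAPMetrics} (AUC is \code{NA}: it is not
#'   derivable from a confusion matrix).
#' @export
metricsFromConfusion <- function(colpct, priors = c(0.5, 0.5)) {
  colpct <- matrix(as.numeric(colpct), 2, 2,
                   dimnames = list(predicted = c("A", "B"),
                                   actual = c("A", "B")))
  bad <- abs(colSums(colpct) - 100) > 0.5
  if (any(bad))
    stop(sprintf("confusion column(s) %s do not sum to 100 within 0.5",
                 paste(c("A", "B")[bad], collapse = ", ")))
  if (abs(sum(priors) - 1) > 1e-9) stop("priors must sum to 1")
  joint <- sweep(colpct / 100, 2, priors, "*")   # P(pred, actual)
  po <- sum(diag(joint))
  pe <- sum(rowSums(joint) * colSums(joint))
  rcl <- colpct["A", "A"] / 100
  pcn <- joint["A", "A"] / sum(joint["A", ])
  f1 <- if (pcn + rcl == 0) 0 else 2 * pcn * rcl / (pcn + rcl)
  new("CAPMetrics", confusion = matrix(NA_real_, 2, 2), colpct = colpct,
      aca = unname(mean(diag(colpct))), pcn = unname(pcn), rcl = unname(rcl),
      f1 = unname(f1), kappa = unname((po - pe) / (1 - pe)))
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' Ties are handled with midranks, so the value equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric scores, larger = more phase-A-like.
#' @param labels factor or character, \code{"A"} positive.
#' @return the AUC in \[0, 1\].
#' @export
aucFromScores <- function(scores, labels) {
  pos <- labels == "A"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
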