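## End-to-end pipeline: preprocess -> segment/balance -> design or load
## filter -> features -> cross-validated evaluation. A single config list
## fully determines a run; the returned report embeds the resolved config.

#' Pipeline configuration
#'
#' @param channels channel labels to use.
#' @param bandpass list with \code{low}, \code{high}, \code{order}.
#' @param analysisRate rate (Hz) the signal is resampled to before
#'   decomposition.
#' @param epochLen epoch length in seconds (1 or 2).
#' @param filter list with \code{L}, \code{p}, \code{levels}, and
#'   optionally \code{path} to a coefficient file to load instead of
#'   designing.
#' @param classifier classifier kind, see \code{\link{trainClassifier}}.
#' @param classifierParams hyperparameter overrides.
#' @param folds cross-validation folds.
#' @param seeds named list of the four stage seeds: \code{balance},
#'   \code{cv}, \code{model} (reserved), \code{synth}.
#' @return config list for \code{\link{runCapPipeline}}.
#' @export
capPipelineConfig <- function(channels = c("C4-A1", "F4-C4"),
                              bandpass = list(low = 0.5, high = 35, order = 4),
                              analysisRate = 64,
                              epochLen = 2,
                              filter = list(L = 12L, p = 4L, levels = 5L),
                              classifier = "bagged_trees",
                              classifierParams = list(),
                              folds = 10L,
                              seeds = list(balance = 11L, cv = 12L,
                                           model = 13L, synth = 14L)) {
  list(channels = channels, bandpass = bandpass, analysisRate = analysisRate,
       epochLen = epochLen, filter = filter, classifier = classifier,
       classifierParams = classifierParams, folds = folds, seeds = seeds)
}

#' Run the CAP phase classification pipeline
#'
#' Accepts either an \linkS4class{EpochSet} (already segmented, e.g. from
#' \code{\link{simulateEpochSet}}) or a recording (list of
#' \linkS4class{EEGTimeSeries} plus an annotation data frame). The stages
#' are: channel preprocessing (bandpass, per-channel min-max normalization,
#' resampling to the analysis rate), segmentation and class balancing,
#' filter-bank design (or load), feature extraction, and stratified k-fold
#' cross-validation of the configured classifier.
#'
#' @param cfg config from \code{\link{capPipelineConfig}}.
#' @param epochs an \linkS4class{EpochSet}, mutually exclusive with
#'   \code{recording}.
#' @param recording list with \code{channels} (list of
#'   \linkS4class{EEGTimeSeries}) and \code{annotations} (data frame).
#' @param balance undersample to equal class counts before training.
#' @param verbose log stage parameters and row counts.
#' @return list with \code{metrics} (a \linkS4class{CAPMetrics}),
#'   \code{features} (a \linkS4class{CAPFeatureSet}), \code{filterBank} and
#'   \code{config}.
#' @export
runCapPipeline <- function(cfg = capPipelineConfig(), epochs = NULL,
                           recording = NULL, balance = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(epochs) == is.null(recording))
    stop("provide exactly one of 'epochs' or 'recording'")

  if (!is.null(recording)) {
    chans <- stage("preprocess", {
      labs <- vapply(recording$channels, function(ch) ch@label, "")
      miss <- setdiff(cfg$channels, labs)
      if (length(miss))
        stop("channel(s) missing from recording: ", paste(miss, collapse = ", "))
      lapply(recording$channels[match(cfg$channels, labs)], function(ch)
        preprocessChannel(ch, low = cfg$bandpass$low, high = cfg$bandpass$high,
                          order = cfg$bandpass$order, fsOut = cfg$analysisRate))
    })
    say("preprocess: %d channels at %g Hz", length(chans), cfg$analysisRate)
    epochs <- stage("segment",
      labelAndSegment(chans, recording$annotations, epochLen = cfg$epochLen))
  } else {
    stopifnot(is(epochs, "EpochSet"))
    if (epochs@fs != cfg$analysisRate)
      epochs <- stage("preprocess",
        preprocessEpochs(epochs, low = cfg$bandpass$low,
                         high = cfg$bandpass$high, order = cfg$bandpass$order,
                         fsOut = cfg$analysisRate))
  }
  say("segment: %d epochs (%d A / %d B)", length(epochs@labels),
      sum(epochs@labels == "A"), sum(epochs@labels == "B"))
  if (balance) {
    epochs <- stage("balance", balanceClasses(epochs, seed = cfg$seeds$balance))
    say("balance: %d epochs retained", length(epochs@labels))
  }
  fb <- stage("filter", {
    if (!is.null(cfg$filter$path)) readFilterBank(cfg$filter$path)
    else designMinBandwidthFilter(cfg$filter$L, cfg$filter$p, cfg$filter$levels)
  })
  feats <- stage("features", extractFeatures(epochs, fb))
  say("features: %d x %d", nrow(featureMatrix(feats)), ncol(featureMatrix(feats)))
  metrics <- stage("evaluate",
    crossValidate(cfg$classifier, feats, k = cfg$folds, seed = cfg$seeds$cv,
                  params = cfg$classifierParams))
  say("evaluate: ACA %.2f%%, kappa %.2f", metrics@aca, metrics@kappa)
  list(metrics = metrics, features = feats, filterBank = fb, config = cfg)
}

#' Serialize a metrics report to JSON
#'
#' @param result list returned by \code{\link{runCapPipeline}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(result, path) {
  m <- result$metrics
  rep <- list(config = result$config,
              confusion_counts = m@confusion,
              confusion_colpct = m@colpct,
              aca = m@aca, pcn = m@pcn, rcl = m@rcl, f1 = m@f1,
              kappa = m@kappa, auc = m@auc,
              fold_accuracy = m@foldAccuracy)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
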