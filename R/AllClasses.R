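#' @import methods
NULL

#' Single-channel EEG trace
#'
#' A thin container for one EEG channel: the sample vector, its sampling
#' rate and the montage label (e.g. \code{"C4-A1"} or \code{"F4-C4"}).
#' Samples are in microvolts on input and dimensionless in \[0, 1\] after
#' \code{\link{minmaxNormalize}}.
#'
#' @slot samples numeric vector of samples.
#' @slot fs sampling rate in Hz.
#' @slot label channel label.
#' @export
setClass("EEGTimeSeries",
  representation(samples = "numeric", fs = "numeric", label = "character"),
  prototype(label = NA_character_),
  validity = function(object) {
    msg <- NULL
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
      msg <- c(msg, "samples must all be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Orthogonal two-channel wavelet filter bank
#'
#' Lowpass/highpass conjugate-quadrature pair together with the dyadic
#' decomposition depth. The highpass is tied to the lowpass by
#' \code{g[n] = (-1)^n h[L-1-n]}. Validity enforces the orthonormal DWT
#' conventions: \code{sum(h) = sqrt(2)}, double-shift orthogonality of
#' \code{h}, and \code{sum(g) = 0}.
#'
#' @slot h numeric, lowpass (scaling) coefficients, even length.
#' @slot g numeric, highpass (wavelet) coefficients.
#' @slot levels integer, decomposition depth.
#' @slot vanishingMoments integer, vanishing moments of the highpass.
#' @export
setClass("WaveletFilterBank",
  representation(h = "numeric", g = "numeric", levels = "integer",
                 vanishingMoments = "integer"),
  validity = function(object) {
    msg <- NULL
    L <- length(object@h)
    if (L < 2L || L %% 2L != 0L) msg <- c(msg, "h must have even length >= 2")
    if (length(object@g) != L) msg <- c(msg, "g must match h in length")
    if (abs(sum(object@h) - sqrt(2)) > 1e-6)
      msg <- c(msg, "sum(h) must equal sqrt(2) within 1e-6")
    if (abs(sum(object@g)) > 1e-6)
      msg <- c(msg, "sum(g) must equal 0 within 1e-6")
    for (k in 0:(L / 2L - 1L)) {
      v <- sum(object@h[1:(L - 2 * k)] * object@h[(1 + 2 * k):L])
      if (abs(v - as.numeric(k == 0)) > 1e-6) {
        msg <- c(msg, sprintf("double-shift orthogonality fails at lag %d", 2 * k))
        break
      }
    }
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Dyadic subband decomposition of one epoch
#'
#' Ordered coefficient sequences \code{[D1, ..., Dlevels, A]} produced by
#' \code{\link{dwt}}, with the dyadic frequency interval of each subband.
#'
#' @slot coeffs list of numeric vectors, finest detail first, approximation
#'   last.
#' @slot ranges two-column matrix (low, high) of per-subband frequency
#'   intervals in Hz.
#' @slot fs sampling rate of the analyzed signal in Hz.
#' @export
setClass("SubbandSet",
  representation(coeffs = "list", ranges = "matrix", fs = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@ranges) != length(object@coeffs))
      msg <- c(msg, "ranges must have one row per subband")
    if (is.null(msg)) TRUE else msg
  })

#' Labeled fixed-length EEG epochs
#'
#' Epochs are stored as an array with dimensions
#' \code{n_epochs x n_samples x n_channels}; the phase label of each epoch
#' ("A" or "B") and the subject id travel alongside.
#'
#' @slot data three-dimensional numeric array, channel names on the third
#'   dimension.
#' @slot labels factor with levels \code{c("A", "B")}, one per epoch.
#' @slot epochLen epoch length in seconds.
#' @slot fs sampling rate in Hz.
#' @slot subject character vector, one id per epoch.
#' @export
setClass("EpochSet",
  representation(data = "array", labels = "factor", epochLen = "numeric",
                 fs = "numeric", subject = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
    else {
      if (d[1] != length(object@labels))
        msg <- c(msg, "one label per epoch required")
      if (abs(d[2] - object@epochLen * object@fs) > 1e-9)
        msg <- c(msg, "n_samples must equal epochLen * fs exactly")
      if (length(object@subject) != d[1])
        msg <- c(msg, "one subject id per epoch required")
    }
    if (!identical(levels(object@labels), c("A", "B")))
      msg <- c(msg, 'labels must be a factor with levels c("A", "B")')
    if (is.null(msg)) TRUE else msg
  })

#' Epoch-by-feature matrix with phase labels
#'
#' A \linkS4class{SummarizedExperiment} with one assay named
#' \code{"features"} (features in rows, epochs in columns) and the phase
#' label of each epoch in \code{colData()$phase}. Feature names follow the
#' pattern \code{"{channel}.{subband}.{feature}"}.
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("CAPFeatureSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, 'an assay named "features" is required')
    else if (any(!is.finite(SummarizedExperiment::assay(object, "features"))))
      msg <- c(msg, "all feature values must be finite")
    cd <- SummarizedExperiment::colData(object)
    if (!"phase" %in% colnames(cd))
      msg <- c(msg, 'colData must contain a "phase" column')
    if (is.null(msg)) TRUE else msg
  })

#' Classification performance summary
#'
#' Pooled 2x2 confusion matrix (counts and column-normalized percentages,
#' columns = actual class as in clinical CAP reports) plus the derived
#' metrics: average classification accuracy (percent), precision, recall,
#' F1, Cohen's kappa and ROC AUC.
#'
#' @slot confusion 2x2 count matrix, predicted in rows, actual in columns.
#' @slot colpct 2x2 column-percentage matrix.
#' @slot aca average classification accuracy in percent.
#' @slot pcn precision for phase A.
#' @slot rcl recall for phase A.
#' @slot f1 F1 score for phase A.
#' @slot kappa Cohen's kappa.
#' @slot auc area under the ROC curve (NA when no scores are available).
#' @slot foldAccuracy per-fold accuracies from cross-validation (may be
#'   empty).
#' @export
setClass("CAPMetrics",
  representation(confusion = "matrix", colpct = "matrix", aca = "numeric",
                 pcn = "numeric", rcl = "numeric", f1 = "numeric",
                 kappa = "numeric", auc = "numeric", foldAccuracy = "numeric"),
  prototype(auc = NA_real_, foldAccuracy = numeric(0)))

#' Fitted CAP phase classifier
#'
#' @slot kind classifier family, one of \code{"bagged_trees"},
#'   \code{"boosted_trees"}, \code{"svm_rbf"}, \code{"knn"},
#'   \code{"logistic"}, \code{"fine_tree"}.
#' @slot fit fitted model object (opaque; for \code{"knn"} the training set
#'   itself).
#' @slot params hyperparameters used.
#' @slot featureNames training feature names, enforced at prediction.
#' @export
setClass("CAPModel",
  representation(kind = "character", fit = "ANY", params = "list",
                 featureNames = "character"))
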