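#' Accessors for filter banks
#'
#' @param fb a \linkS4class{WaveletFilterBank}.
#' @return numeric coefficient vector.
#' @export
lowpass <- function(fb) fb@h

#' @rdname lowpass
#' @export
highpass <- function(fb) fb@g

#' @rdname lowpass
#' @export
decompositionLevels <- function(fb) fb@levels

setMethod("show", "EEGTimeSeries", function(object) {
  cat(sprintf("EEGTimeSeries '%s': %d samples at %g Hz (%.1f s)\n",
              object@label, length(object@samples), object@fs,
              length(object@samples) / object@fs))
})

setMethod("show", "WaveletFilterBank", function(object) {
  bw <- rmsBandwidth(object@h)
  cat(sprintf("WaveletFilterBank: length %d, %d vanishing moments, %d levels\n",
              length(object@h), object@vanishingMoments, object@levels))
  cat(sprintf("  RMS bandwidth: %.5f rad/sample (B^2 = %.5f)\n", bw$b, bw$b_sq))
  cat("  h:", paste(sprintf("% .5f", object@h), collapse = " "), "\n")
})

setMethod("show", "SubbandSet", function(object) {
  cat(sprintf("SubbandSet: %d subbands (fs = %g Hz)\n",
              length(object@coeffs), object@fs))
  for (i in seq_along(object@coeffs))
    cat(sprintf("  %-3s %4d coefficients  %g-%g Hz\n",
                names(object@coeffs)[i], length(object@coeffs[[i]]),
                object@ranges[i, 1], object@ranges[i, 2]))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d samples x %d channel(s), %g s at %g Hz\n",
              d[1], d[2], d[3], object@epochLen, object@fs))
  cat(sprintf("  phase A: %d, phase B: %d\n",
              sum(object@labels == "A"), sum(object@labels == "B")))
})

setMethod("show", "CAPMetrics", function(object) {
  cat("CAP phase classification metrics\n")
  if (!anyNA(object@confusion)) {
    cat("  confusion (counts, predicted x actual):\n")
    print(object@confusion)
  }
  cat("  column % (per actual class):\n")
  print(round(object@colpct, 2))
  cat(sprintf("  ACA %.2f%%  Pcn %.2f  Rcl %.2f  F1 %.2f  kappa %.2f  AUC %s\n",
              object@aca, object@pcn, object@rcl, object@f1, object@kappa,
              ifelse(is.na(object@auc), "NA", sprintf("%.2f", object@auc))))
})

setMethod("show", "CAPModel", function(object) {
  cat(sprintf("CAPModel: %s on %d features\n", object@kind,
              length(object@featureNames)))
})
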