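## Subband features: wavelet entropy and the three Hjorth parameters,
## computed on each of the levels+1 subbands of every epoch and channel.
## With 6 subbands x 4 features this gives 24 features per channel and 48
## for the two-channel montage pair.

#' Wavelet entropy of a coefficient sequence
#'
#' \code{E = -sum_i |c_i| log|c_i|} with the natural logarithm and the
#' convention \code{0 log 0 = 0}. By default the coefficient magnitudes are
#' used directly (no probability normalization); set
#' \code{normalize = TRUE} for the Shannon form on
#' \code{p_i = |c_i| / sum_j |c_j|}.
#'
#' @param c numeric coefficient vector.
#' @param normalize logical; default \code{FALSE}.
#' @return the entropy value.
#' @export
waveletEntropy <- function(c, normalize = FALSE) {
  x <- abs(c)
  if (normalize) {
    s <- sum(x)
    if (s == 0) return(0)
    x <- x / s
  }
  nz <- x > 0
  -sum(x[nz] * log(x[nz]))
}

popVar <- function(x) mean((x - mean(x))^2)

#' Hjorth parameters
#'
#' Time-domain EEG descriptors: activity is the (population) variance of
#' the signal; mobility is the ratio of the standard deviation of the first
#' difference to that of the signal (a mean-frequency proxy); complexity is
#' the mobility of the first difference divided by the mobility of the
#' signal (a bandwidth proxy). Derivatives are first differences without
#' sampling-rate scaling.
#'
#' @param x numeric signal (length >= 3 for complexity).
#' @return the parameter value.
#' @export
hjorthActivity <- function(x) popVar(x)

#' @rdname hjorthActivity
#' @export
hjorthMobility <- function(x) {
  v <- popVar(x)
  if (v == 0) stop("constant input: mobility undefined")
  sqrt(popVar(diff(x)) / v)
}

#' @rdname hjorthActivity
#' @export
hjorthComplexity <- function(x) {
  if (length(x) < 3) stop("complexity needs at least 3 samples")
  hjorthMobility(diff(x)) / hjorthMobility(x)
}

subbandFeatures <- function(cc) {
  act <- hjorthActivity(cc)
  if (act == 0) {
    ## degenerate (constant) subband: keep the vector finite for the
    ## classifier, report 0 rather than NaN
    warning("degenerate constant subband: mobility/complexity set to 0")
    mob <- 0; cpx <- 0
  } else {
    mob <- hjorthMobility(cc)
    vd <- popVar(diff(cc))
    cpx <- if (vd == 0) { warning("degenerate subband derivative: complexity set to 0"); 0 }
           else hjorthComplexity(cc)
  }
  c(entropy = waveletEntropy(cc), activity = act, mobility = mob,
    complexity = cpx)
}

#' Feature vector of one epoch
#'
#' Decomposes each channel with the filter bank and computes, per subband in
#' the fixed order \code{D1..Dlevels, A}, the quadruple
#' \code{[entropy, activity, mobility, complexity]}; channels are
#' concatenated in their input order. Names follow
#' \code{"{channel}.{subband}.{feature}"}.
#'
#' @param epoch numeric matrix \code{n_samples x n_channels} (or a vector
#'   for one channel).
#' @param fb a \linkS4class{WaveletFilterBank}.
#' @param channelNames labels used in feature names.
#' @return named numeric vector of length \code{(levels+1) * 4 *
#'   n_channels}.
#' @export
extractEpochFeatures <- function(epoch, fb, channelNames = NULL) {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, ncol = 1)
  nc <- ncol(epoch)
  if (is.null(channelNames)) channelNames <- colnames(epoch)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nc))
  out <- numeric(0)
  for (ci in seq_len(nc)) {
    s <- suppressWarnings(dwt(epoch[, ci], fb))
    f <- unlist(lapply(s@coeffs, subbandFeatures))
    names(f) <- paste(channelNames[ci],
                      rep(names(s@coeffs), each = 4),
                      rep(c("entropy", "activity", "mobility", "complexity"),
                          length(s@coeffs)), sep = ".")
    out <- c(out, f)
  }
  out
}

#' Feature extraction for an epoch set
#'
#' Applies \code{\link{extractEpochFeatures}} to every epoch of an
#' \linkS4class{EpochSet} and assembles a \linkS4class{CAPFeatureSet}
#' (features in rows, epochs in columns, phase labels in
#' \code{colData()$phase}).
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param fb a \linkS4class{WaveletFilterBank}.
#' @return a \linkS4class{CAPFeatureSet}.
#' @export
extractFeatures <- function(epochs, fb) {
  stopifnot(is(epochs, "EpochSet"), is(fb, "WaveletFilterBank"))
  n <- dim(epochs@data)[1]
  if (n == 0) stop("empty epoch set")
  chn <- dimnames(epochs@data)[[3]]
  first <- extractEpochFeatures(epochs@data[1, , ], fb, channelNames = chn)
  mat <- matrix(0, length(first), n,
                dimnames = list(names(first), NULL))
  mat[, 1] <- first
  if (n > 1) for (i in 2:n)
    mat[, i] <- extractEpochFeatures(epochs@data[i, , ], fb, channelNames = chn)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    colData = S4Vectors::DataFrame(phase = epochs@labels,
                                   subject = epochs@subject))
  new("CAPFeatureSet", se)
}

#' Feature matrix and labels from a CAPFeatureSet
#'
#' @param x a \linkS4class{CAPFeatureSet}.
#' @return \code{featureMatrix}: epochs-by-features numeric matrix;
#'   \code{phaseLabels}: factor of phases.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @rdname featureMatrix
#' @export
phaseLabels <- function(x) SummarizedExperiment::colData(x)$phase

#' Kruskal-Wallis feature ranking
#'
#' Ranks every feature by the (tie-corrected) Kruskal-Wallis H statistic of
#' phase A versus phase B, with the p-value from the chi-square reference
#' with one degree of freedom. Rank 1 is the smallest p; ties break by
#' descending H, then by feature index.
#'
#' @param x a \linkS4class{CAPFeatureSet} with both classes present
#'   (\code{>= 2} epochs each).
#' @return data frame with \code{feature}, \code{H}, \code{p_value},
#'   \code{rank}.
#' @export
rankFeatures <- function(x) {
  mat <- featureMatrix(x)
  lab <- phaseLabels(x)
  if (any(table(lab) < 2)) stop("each class needs at least 2 epochs")
  H <- numeric(ncol(mat)); p <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    if (length(unique(mat[, j])) == 1L) { H[j] <- 0; p[j] <- 1; next }
    kt <- kruskal.test(mat[, j], lab)
    H[j] <- unname(kt$statistic)
    p[j] <- kt$p.value
  }
  ord <- order(p, -H, seq_along(p))
  rk <- integer(length(p)); rk[ord] <- seq_along(p)
  data.frame(feature = colnames(mat), H = H, p_value = p, rank = rk,
             stringsAsFactors = FALSE)
}
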