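## Channel-level preprocessing. The fixed pipeline order is
## bandpass -> normalize -> resample -> segment: the 0.5-35 Hz band keeps the
## clinically relevant EEG content, min-max normalization is applied once per
## channel per recording so that phase-A bursts keep their amplitude relative
## to background, and resampling to 64 Hz makes five dyadic halvings land
## exactly on the 0-1 ... 16-32 Hz subband ladder.

#' Construct an EEG time series
#'
#' @param samples numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param label channel label, e.g. \code{"C4-A1"}.
#' @return an \linkS4class{EEGTimeSeries}.
#' @export
eegTimeSeries <- function(samples, fs, label = NA_character_) {
  new("EEGTimeSeries", samples = as.numeric(samples), fs = as.numeric(fs),
      label = as.character(label))
}

asSamples <- function(x) if (is(x, "EEGTimeSeries")) x@samples else as.numeric(x)

rewrap <- function(x, samples, fs = NULL) {
  if (is(x, "EEGTimeSeries")) {
    out <- x
    out@samples <- samples
    if (!is.null(fs)) out@fs <- fs
    validObject(out)
    out
  } else samples
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-\code{order} Butterworth bandpass applied forward-backward
#' (zero phase, so the effective magnitude order doubles). Defaults follow
#' AASM practice for sleep EEG: 0.5-35 Hz, order 4.
#'
#' @param x an \linkS4class{EEGTimeSeries}, or a numeric vector with
#'   \code{fs} given.
#' @param low,high cutoff frequencies in Hz, \code{0 < low < high < fs/2}.
#' @param order Butterworth order of the single-pass prototype.
#' @param fs sampling rate in Hz when \code{x} is a bare vector.
#' @return same type as \code{x}, filtered.
#' @export
bandpassFilter <- function(x, low = 0.5, high = 35, order = 4, fs = NULL) {
  if (is(x, "EEGTimeSeries")) fs <- x@fs
  if (is.null(fs)) stop("fs is required when x is a plain numeric vector")
  if (!(low > 0 && low < high && high < fs / 2))
    stop(sprintf("cutoffs must satisfy 0 < low < high < fs/2 = %g", fs / 2))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, asSamples(x))
  rewrap(x, y)
}

#' Min-max amplitude normalization
#'
#' \code{(x - min) / (max - min)}: scales a channel into \[0, 1\] exactly.
#' Applied once per channel per recording, never per epoch, so relative
#' amplitude differences between phase-A bursts and background survive.
#'
#' @param x an \linkS4class{EEGTimeSeries} or numeric vector.
#' @return same type as \code{x}, normalized.
#' @export
minmaxNormalize <- function(x) {
  v <- asSamples(x)
  rng <- range(v)
  if (diff(rng) == 0) stop("constant signal: zero range, cannot normalize")
  rewrap(x, (v - rng[1]) / diff(rng))
}

#' Anti-aliased resampling by Fourier (sinc) interpolation
#'
#' Spectrum-truncation resampling: the signal's Fourier coefficients above
#' the new Nyquist rate are discarded and the remainder inverted at the new
#' length, which is exact for band-limited content and inherently
#' anti-aliased. The default target of 64 Hz is the analysis rate at which
#' a five-level dyadic decomposition spans exactly 0-32 Hz.
#'
#' @param x an \linkS4class{EEGTimeSeries}, or numeric vector with
#'   \code{fs}.
#' @param fsOut output rate in Hz, \code{fsOut <= fs}; the implied output
#'   length \code{n * fsOut / fs} must be an integer.
#' @param fs input rate when \code{x} is a bare vector.
#' @return same type as \code{x} at the new rate.
#' @export
resampleTo <- function(x, fsOut = 64, fs = NULL) {
  if (is(x, "EEGTimeSeries")) fs <- x@fs
  if (is.null(fs)) stop("fs is required when x is a plain numeric vector")
  if (fsOut > fs) stop("fsOut must not exceed the input rate")
  if (fsOut == fs) return(x)
  v <- asSamples(x)
  y <- fftResample(v, fs, fsOut)
  rewrap(x, y, fs = fsOut)
}

fftResample <- function(v, fs, fsOut) {
  n <- length(v)
  nOutR <- n * fsOut / fs
  if (abs(nOutR - round(nOutR)) > 1e-9)
    stop(sprintf("length %d at %g -> %g Hz gives a non-integer output length", n, fs, fsOut))
  nout <- as.integer(round(nOutR))
  X <- fft(v)
  keep <- nout %/% 2L
  Y <- complex(length.out = nout)
  Y[1] <- X[1]
  if (keep >= 2) {
    Y[2:keep] <- X[2:keep]
    Y[nout - (1:(keep - 1)) + 1L] <- X[n - (1:(keep - 1)) + 1L]
  }
  if (nout %% 2L == 0L && keep + 1L <= n)
    Y[keep + 1L] <- Re(X[keep + 1L])          # split Nyquist bin
  Re(fft(Y, inverse = TRUE)) / n
}

#' Full channel preprocessing chain
#'
#' \code{bandpass -> minmax normalize -> resample}, the fixed order used
#' throughout the pipeline.
#'
#' @param x an \linkS4class{EEGTimeSeries}.
#' @param low,high,order bandpass settings, see \code{\link{bandpassFilter}}.
#' @param fsOut analysis rate, see \code{\link{resampleTo}}.
#' @return preprocessed \linkS4class{EEGTimeSeries}.
#' @export
preprocessChannel <- function(x, low = 0.5, high = 35, order = 4, fsOut = 64) {
  x <- bandpassFilter(x, low = low, high = high, order = order)
  x <- minmaxNormalize(x)
  resampleTo(x, fsOut = fsOut)
}
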