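## Dyadic analysis/synthesis with an arbitrary orthogonal filter pair.
## Periodic boundary extension throughout: it preserves orthogonality (hence
## Parseval and perfect reconstruction) and gives exact coefficient counts
## N/2^j on short epochs. The filter may be longer than the signal at deep
## levels; indices then wrap multiple times, which keeps the transform
## orthogonal because all non-zero even autocorrelation lags vanish.

analysisStep <- function(x, h, g) {
  N <- length(x)
  half <- N %/% 2L
  a <- numeric(half); d <- numeric(half)
  n0 <- 2L * (0:(half - 1L))
  for (k in seq_along(h)) {
    idx <- (n0 + (k - 1L)) %% N + 1L
    a <- a + h[k] * x[idx]
    d <- d + g[k] * x[idx]
  }
  list(a = a, d = d)
}

synthesisStep <- function(a, d, h, g) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  n0 <- 2L * (0:(half - 1L))
  for (k in seq_along(h)) {
    idx <- (n0 + (k - 1L)) %% N + 1L   # distinct for fixed k (stride-2 ring)
    x[idx] <- x[idx] + h[k] * a + g[k] * d
  }
  x
}

#' Dyadic frequency ranges of the subbands
#'
#' Dyadic halving of \code{[0, fs/2]}: detail subband \code{Dj} covers
#' \code{(fs/2^(j+1), fs/2^j)} and the approximation covers
#' \code{(0, fs/2^(levels+1))}. At 64 Hz and 5 levels this is the ladder
#' 16-32, 8-16, 4-8, 2-4, 1-2 and 0-1 Hz.
#'
#' @param fs sampling rate in Hz.
#' @param levels decomposition depth.
#' @return two-column matrix (low, high) with rows \code{D1..Dlevels, A}.
#' @export
subbandRanges <- function(fs, levels) {
  hi <- fs / 2^(1:levels)
  lo <- fs / 2^(2:(levels + 1))
  m <- rbind(cbind(lo, hi), c(0, fs / 2^(levels + 1)))
  dimnames(m) <- list(c(paste0("D", 1:levels), paste0("A", levels)),
                      c("low", "high"))
  m
}

#' Dyadic wavelet analysis
#'
#' Iterated two-channel filtering and downsampling with periodic extension.
#' A \code{levels}-deep decomposition of \code{N} samples returns
#' \code{levels + 1} subbands \code{[D1, ..., Dlevels, A]} of lengths
#' \code{N/2, N/4, ..., N/2^levels, N/2^levels}; the lowest band is the
#' approximation coefficients, the rest are detail coefficients.
#'
#' @param x numeric samples or an \linkS4class{EEGTimeSeries}; the length
#'   must be divisible by \code{2^levels}.
#' @param fb a \linkS4class{WaveletFilterBank}.
#' @param fs sampling rate in Hz (taken from \code{x} when it is an
#'   \linkS4class{EEGTimeSeries}).
#' @return a \linkS4class{SubbandSet}.
#' @export
dwt <- function(x, fb, fs = NA_real_) {
  stopifnot(is(fb, "WaveletFilterBank"))
  if (is(x, "EEGTimeSeries")) { fs <- x@fs; x <- x@samples }
  levels <- fb@levels
  if (length(x) %% 2^levels != 0)
    stop(sprintf("signal length %d is not divisible by 2^levels = %d",
                 length(x), 2^levels))
  details <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    st <- analysisStep(cur, fb@h, fb@g)
    details[[j]] <- st$d
    cur <- st$a
  }
  coeffs <- c(details, list(cur))
  names(coeffs) <- c(paste0("D", 1:levels), paste0("A", levels))
  ranges <- if (is.na(fs)) matrix(NA_real_, levels + 1, 2) else subbandRanges(fs, levels)
  new("SubbandSet", coeffs = coeffs, ranges = ranges, fs = as.numeric(fs))
}

#' Dyadic wavelet synthesis (inverse transform)
#'
#' @param s a \linkS4class{SubbandSet} produced by \code{\link{dwt}} with
#'   the same filter bank.
#' @param fb the \linkS4class{WaveletFilterBank} used for analysis.
#' @return numeric vector of reconstructed samples.
#' @export
idwt <- function(s, fb) {
  stopifnot(is(s, "SubbandSet"), is(fb, "WaveletFilterBank"))
  levels <- fb@levels
  if (length(s@coeffs) != levels + 1L)
    stop(sprintf("subband count %d does not match levels + 1 = %d",
                 length(s@coeffs), levels + 1L))
  cur <- s@coeffs[[levels + 1L]]
  for (j in rev(seq_len(levels)))
    cur <- synthesisStep(cur, s@coeffs[[j]], fb@h, fb@g)
  cur
}

#' Per-subband energies
#'
#' @param s a \linkS4class{SubbandSet}.
#' @return named numeric vector of sums of squared coefficients.
#' @export
subbandEnergies <- function(s) {
  vapply(s@coeffs, function(cc) sum(cc^2), 0.0)
}
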