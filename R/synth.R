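## Synthetic sleep-EEG generator. The minimal generative model mirrors the
## qualitative phase descriptions: phase B is band-limited 1/f^beta
## ("pink") background of unit RMS; phase A is the same background plus
## either a raised-cosine-windowed delta-band (0.5-4 Hz) burst or, with
## some probability, a biphasic K-complex-like transient of about 0.8 s.
## The burst peak amplitude is (amp_ratio - 1) x background RMS, so
## amp_ratio = 1 means phase A and phase B share literally the same law and
## amp_ratio is the approximate ratio of phase-A envelope to background.
## Two channels share half their background variance (a common cortical
## source plus channel-specific noise); transients are common to both.

#' Synthetic generator parameters
#'
#' @param fs sampling rate in Hz.
#' @param epochLen epoch length in seconds.
#' @param nEpochs epochs per class.
#' @param ampRatio phase-A burst-to-background amplitude ratio (>= 1; 1
#'   makes the classes identically distributed).
#' @param backgroundExponent spectral slope beta of the 1/f^beta background.
#' @param kComplexProb probability that a phase-A epoch carries a biphasic
#'   transient instead of a delta burst.
#' @param sharedVariance fraction of background variance common to the two
#'   channels.
#' @param channels channel labels.
#' @param seed integer RNG seed.
#' @return named list of parameters.
#' @export
synthParams <- function(fs = 512, epochLen = 2, nEpochs = 1000, ampRatio = 5,
                        backgroundExponent = 1, kComplexProb = 0.2,
                        sharedVariance = 0.5,
                        channels = c("C4-A1", "F4-C4"), seed = 1L) {
  if (ampRatio < 1) stop("ampRatio must be >= 1")
  if (kComplexProb < 0 || kComplexProb > 1) stop("kComplexProb must be in [0, 1]")
  if (sharedVariance < 0 || sharedVariance > 1) stop("sharedVariance must be in [0, 1]")
  list(fs = fs, epochLen = epochLen, nEpochs = nEpochs, ampRatio = ampRatio,
       backgroundExponent = backgroundExponent, kComplexProb = kComplexProb,
       sharedVariance = sharedVariance, channels = channels,
       seed = as.integer(seed))
}

## one band-limited 1/f^beta noise trace of length n at rate fs, unit RMS
pinkNoise <- function(n, fs, beta, band = c(0.5, 35)) {
  freqs <- seq(0, fs / 2, by = fs / n)
  nf <- length(freqs)
  amp <- numeric(nf)
  inb <- freqs >= band[1] & freqs <= band[2]
  amp[inb] <- freqs[inb]^(-beta / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  spec[1] <- 0
  full <- complex(length.out = n)
  full[1:nf] <- spec
  if (n %% 2 == 0) {
    full[nf] <- complex(modulus = Mod(spec[nf]), argument = 0)
    if (nf > 2) full[(nf + 1):n] <- Conj(spec[(nf - 1):2])
  } else {
    full[(nf + 1):n] <- Conj(spec[nf:2])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

deltaBurst <- function(n, fs, amp) {
  f <- runif(1, 0.5, 4)
  t <- (0:(n - 1)) / fs
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))   # raised cosine
  amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) * win
}

kComplexTransient <- function(n, fs, amp) {
  dur <- 0.8
  m <- min(n, as.integer(round(dur * fs)))
  t0 <- if (n > m) sample.int(n - m, 1) else 1L
  tt <- (0:(m - 1)) / fs
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  shape <- sin(2 * pi * tt / dur) * win                    # biphasic
  out <- numeric(n)
  out[t0:(t0 + m - 1)] <- amp * shape
  out
}

#' Generate a labeled synthetic epoch set
#'
#' Produces \code{nEpochs} phase-A and \code{nEpochs} phase-B epochs per
#' the generative model above; deterministic for a given seed.
#'
#' @param p parameter list from \code{\link{synthParams}}.
#' @return an \linkS4class{EpochSet} (labels A then B).
#' @export
simulateEpochSet <- function(p = synthParams()) {
  n <- as.integer(round(p$fs * p$epochLen))
  nc <- length(p$channels)
  nTot <- 2L * p$nEpochs
  dat <- array(0, dim = c(nTot, n, nc),
               dimnames = list(NULL, NULL, p$channels))
  withSeed(p$seed, {
    sh <- sqrt(p$sharedVariance); ind <- sqrt(1 - p$sharedVariance)
    for (ei in seq_len(nTot)) {
      src <- pinkNoise(n, p$fs, p$backgroundExponent)
      isA <- ei <= p$nEpochs
      transient <- if (!isA || p$ampRatio == 1) numeric(n)
        else if (runif(1) < p$kComplexProb)
          kComplexTransient(n, p$fs, p$ampRatio - 1)
        else deltaBurst(n, p$fs, p$ampRatio - 1)
      for (ci in seq_len(nc)) {
        bg <- sh * src + ind * pinkNoise(n, p$fs, p$backgroundExponent)
        dat[ei, , ci] <- bg + transient
      }
    }
  })
  new("EpochSet", data = dat,
      labels = factor(rep(c("A", "B"), each = p$nEpochs), levels = c("A", "B")),
      epochLen = p$epochLen, fs = p$fs,
      subject = rep("synthetic", nTot))
}

#' Generate an annotated continuous recording
#'
#' Builds a continuous two-channel recording from a layout of phase-A
#' intervals: A intervals carry phase-A texture (delta burst riding on
#' background), everything else is background. The returned annotations
#' reproduce the layout exactly.
#'
#' @param p parameter list from \code{\link{synthParams}}.
#' @param layout data frame with columns \code{onset}, \code{duration}
#'   (seconds) of phase-A events; durations must lie in \[2, 60\] s.
#' @param totalDuration recording length in seconds (default: covers the
#'   layout plus 30 s).
#' @return list with \code{channels} (list of \linkS4class{EEGTimeSeries})
#'   and \code{annotations} (data frame of A1 events).
#' @export
simulateRecording <- function(p = synthParams(), layout, totalDuration = NULL) {
  if (any(layout$duration < 2 - 1e-9 | layout$duration > 60 + 1e-9))
    stop("layout phase durations must lie in [2, 60] s")
  if (is.null(totalDuration))
    totalDuration <- max(layout$onset + layout$duration) + 30
  n <- as.integer(round(totalDuration * p$fs))
  withSeed(p$seed, {
    chans <- vector("list", length(p$channels))
    sh <- sqrt(p$sharedVariance); ind <- sqrt(1 - p$sharedVariance)
    src <- pinkNoise(n, p$fs, p$backgroundExponent)
    tex <- numeric(n)
    for (i in seq_len(nrow(layout))) {
      i0 <- as.integer(round(layout$onset[i] * p$fs)) + 1L
      m <- as.integer(round(layout$duration[i] * p$fs))
      tex[i0:(i0 + m - 1L)] <- deltaBurst(m, p$fs, p$ampRatio - 1)
    }
    for (ci in seq_along(p$channels)) {
      bg <- sh * src + ind * pinkNoise(n, p$fs, p$backgroundExponent)
      chans[[ci]] <- eegTimeSeries(bg + tex, fs = p$fs,
                                   label = p$channels[ci])
    }
    list(channels = chans,
         annotations = data.frame(onset = layout$onset,
                                  duration = layout$duration,
                                  label = "A1", stringsAsFactors = FALSE))
  })
}

#' Preprocess an epoch set
#'
#' Applies the channel chain to epoched data: per-epoch zero-phase bandpass,
#' min-max normalization computed per channel across the whole epoch
#' collection (the epoch set plays the role of the recording), and
#' polyphase resampling to the analysis rate.
#'
#' @param e an \linkS4class{EpochSet}.
#' @param low,high,order bandpass settings.
#' @param fsOut analysis rate in Hz.
#' @return a preprocessed \linkS4class{EpochSet} at \code{fsOut}.
#' @export
preprocessEpochs <- function(e, low = 0.5, high = 35, order = 4, fsOut = 64) {
  stopifnot(is(e, "EpochSet"))
  d <- dim(e@data)
  nOut <- as.integer(round(e@epochLen * fsOut))
  out <- array(0, dim = c(d[1], nOut, d[3]), dimnames = dimnames(e@data))
  bf <- signal::butter(order, c(low, high) / (e@fs / 2), type = "pass")
  for (ci in seq_len(d[3])) {
    filt <- matrix(0, d[1], d[2])
    for (ei in seq_len(d[1]))
      filt[ei, ] <- signal::filtfilt(bf, e@data[ei, , ci])
    rng <- range(filt)
    if (diff(rng) == 0) stop("constant channel: cannot normalize")
    filt <- (filt - rng[1]) / diff(rng)
    for (ei in seq_len(d[1]))
      out[ei, , ci] <- fftResample(filt[ei, ], e@fs, fsOut)
  }
  new("EpochSet", data = out, labels = e@labels, epochLen = e@epochLen,
      fs = fsOut, subject = e@subject)
}
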