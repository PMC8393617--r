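## Minimal EDF (European Data Format) codec: 256-byte fixed header,
## 256 bytes per signal, then data records of 16-bit little-endian integers.
## Continuous recordings only; per-channel sampling rates are supported.
## Physical scaling follows the standard affine map between the digital and
## physical min/max declared in the header.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = "-")
}

#' Write channels to an EDF file
#'
#' @param channels list of \linkS4class{EEGTimeSeries} (rates may differ,
#'   but each must give an integer number of samples per data record).
#' @param path output file path.
#' @param recordDuration duration of one data record in seconds.
#' @param startdate,starttime header date/time strings
#'   (\code{"dd.mm.yy"}, \code{"hh.mm.ss"}).
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(channels, path, recordDuration = 1,
                     startdate = "01.01.01", starttime = "00.00.00") {
  stopifnot(length(channels) >= 1)
  ns <- length(channels)
  spr <- vapply(channels, function(ch) ch@fs * recordDuration, 0.0)
  if (any(abs(spr - round(spr)) > 1e-9))
    stop("each channel must have an integer number of samples per record")
  spr <- as.integer(round(spr))
  nrec <- min(floor(vapply(channels, function(ch) length(ch@samples), 0.0) /
                      (vapply(channels, function(ch) ch@fs, 0.0) * recordDuration)))
  if (nrec < 1) stop("recording shorter than one data record")

  phmin <- vapply(channels, function(ch) min(ch@samples), 0.0)
  phmax <- vapply(channels, function(ch) max(ch@samples), 0.0)
  flat <- phmax - phmin <= 0
  phmax[flat] <- phmin[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edfPad(x, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                        # local patient id
  wr("Startdate X X X X", 80)              # local recording id
  wr(startdate, 8); wr(starttime, 8)
  wr(256L * (1L + ns), 8)
  wr("", 44)
  wr(nrec, 8)
  wr(format(recordDuration), 8)
  wr(ns, 4)
  labs <- vapply(channels, function(ch) ifelse(is.na(ch@label), "EEG", ch@label), "")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)        # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phmin[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)        # prefiltering
  for (i in seq_len(ns)) wr(spr[i], 8)
  for (i in seq_len(ns)) wr("", 32)        # reserved

  scale <- (dmax - dmin) / (phmax - phmin)
  for (rec in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      seg <- channels[[i]]@samples[((rec - 1L) * spr[i] + 1L):(rec * spr[i])]
      dig <- as.integer(round((seg - phmin[i]) * scale[i]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read channels from an EDF file
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to extract
#'   (default: all). An error names any requested label that is absent.
#' @return named list of \linkS4class{EEGTimeSeries}, plus attributes
#'   \code{startdate} and \code{starttime}.
#' @export
readEDF <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                    # version
  rd(80); rd(80)
  startdate <- rd(8); starttime <- rd(8)
  rd(8)                                    # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  phmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  want <- if (is.null(channels)) seq_len(ns) else match(channels, labs)
  if (anyNA(want))
    stop("channel(s) not present in EDF: ",
         paste(channels[is.na(want)], collapse = ", "))

  store <- lapply(seq_len(ns), function(i) vector("list", nrec))
  for (rec in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (i %in% want) store[[i]][[rec]] <- dig
    }
  }
  out <- lapply(want, function(i) {
    dig <- unlist(store[[i]])
    phys <- phmin[i] + (dig - dmin[i]) * (phmax[i] - phmin[i]) / (dmax[i] - dmin[i])
    eegTimeSeries(phys, fs = spr[i] / recDur, label = labs[i])
  })
  names(out) <- labs[want]
  attr(out, "startdate") <- startdate
  attr(out, "starttime") <- starttime
  out
}
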