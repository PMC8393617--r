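## CAP scoring rules (Terzano atlas conventions):
##   - phase A and phase B durations lie in [2, 60] s;
##   - two A phases separated by < 2 s merge into one;
##   - a CAP sequence needs at least three A phases in A-B-A-B-A order;
##   - an inter-A gap > 60 s (or a phase outside [2, 60] s) breaks the chain;
##   - an A with no companion B is an isolated phase A and counts as non-CAP;
##   - CAP rate = CAP time / NREM time.
## For the classification task the paper-style shortcut labelling is used
## instead: every annotated (merged) A interval is class A and *all other*
## NREM time is class B. Strict sequence-internal B phases matter only for
## the CAP parameters.

CANONICAL_LABELS <- c("A1", "A2", "A3", "B", "NREM1", "NREM2", "NREM3",
                      "REM", "W")

#' Parse CAP/sleep annotations
#'
#' Two dialects are supported. \code{"simple-tsv"}: tab-separated
#' \code{onset<TAB>duration<TAB>label} with onsets in seconds.
#' \code{"physionet-cap"}: the event-list text files distributed with the
#' CAP Sleep Database (columns including \code{Time [hh:mm:ss]},
#' \code{Event}, \code{Duration[s]}); clock times are converted to seconds
#' from the first event, wrapping past midnight, sleep-stage events
#' \code{SLEEP-S0..S4/REM} map to W/NREM1..3/REM and \code{MCAP-A1..A3} map
#' to A1..A3.
#'
#' @param source file path or character vector of lines.
#' @param dialect \code{"simple-tsv"} or \code{"physionet-cap"}.
#' @return data frame with columns \code{onset}, \code{duration},
#'   \code{label}, sorted by onset. Unknown labels are skipped with a
#'   warning; overlapping events within the A stream are an error.
#' @export
parseAnnotations <- function(source, dialect = c("simple-tsv", "physionet-cap")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source, warn = FALSE)
           else as.character(source)
  ev <- switch(dialect,
               "simple-tsv" = parseSimpleTsv(lines),
               "physionet-cap" = parsePhysionetCap(lines))
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  checkNoOverlap(ev[ev$label %in% c("A1", "A2", "A3"), , drop = FALSE], "phase A")
  ev
}

parseSimpleTsv <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  onset <- numeric(0); duration <- numeric(0); label <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[1]))) ||
        is.na(suppressWarnings(as.numeric(f[2]))))
      stop(sprintf("unparseable annotation line %d: '%s'", i, lines[i]))
    lab <- trimws(f[3])
    if (!lab %in% CANONICAL_LABELS) {
      warning(sprintf("skipping unknown label '%s' (line %d)", lab, i))
      next
    }
    onset <- c(onset, as.numeric(f[1]))
    duration <- c(duration, as.numeric(f[2]))
    label <- c(label, lab)
  }
  validateEvents(data.frame(onset = onset, duration = duration, label = label,
                            stringsAsFactors = FALSE))
}

parsePhysionetCap <- function(lines) {
  body <- lines[nzchar(trimws(lines))]
  hdr <- grep("Sleep Stage", body)
  if (length(hdr)) body <- body[-seq_len(hdr[length(hdr)])]
  stageMap <- c("SLEEP-S0" = "W", "SLEEP-S1" = "NREM1", "SLEEP-S2" = "NREM2",
                "SLEEP-S3" = "NREM3", "SLEEP-S4" = "NREM3", "SLEEP-REM" = "REM",
                "SLEEP-MT" = NA, "MCAP-A1" = "A1", "MCAP-A2" = "A2",
                "MCAP-A3" = "A3")
  onset <- numeric(0); duration <- numeric(0); label <- character(0)
  t0 <- NA_real_; lastT <- NA_real_; dayShift <- 0
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    tm <- grep("^\\d{1,2}[:.]\\d{2}[:.]\\d{2}$", f, value = TRUE)
    if (!length(tm)) stop(sprintf("no clock time on line %d: '%s'", i, body[i]))
    hms <- as.numeric(strsplit(tm[1], "[:.]")[[1]])
    sec <- hms[1] * 3600 + hms[2] * 60 + hms[3]
    if (!is.na(lastT) && sec + dayShift < lastT) dayShift <- dayShift + 86400
    sec <- sec + dayShift
    lastT <- sec
    if (is.na(t0)) t0 <- sec
    evf <- f[f %in% names(stageMap)]
    if (!length(evf)) {
      warning(sprintf("skipping line %d with unknown event", i))
      next
    }
    lab <- stageMap[[evf[1]]]
    if (is.na(lab)) next
    durf <- suppressWarnings(as.numeric(f[length(f) - 1]))
    if (is.na(durf)) {
      nums <- suppressWarnings(as.numeric(f))
      nums <- nums[!is.na(nums)]
      if (!length(nums)) stop(sprintf("no duration on line %d", i))
      durf <- nums[length(nums)]
    }
    onset <- c(onset, sec - t0)
    duration <- c(duration, durf)
    label <- c(label, lab)
  }
  validateEvents(data.frame(onset = onset, duration = duration, label = label,
                            stringsAsFactors = FALSE))
}

validateEvents <- function(ev) {
  if (nrow(ev)) {
    if (any(ev$onset < 0)) stop("negative onset in annotations")
    if (any(ev$duration <= 0)) stop("non-positive duration in annotations")
  }
  ev
}

checkNoOverlap <- function(ev, what) {
  if (nrow(ev) < 2) return(invisible(TRUE))
  ev <- ev[order(ev$onset), ]
  ends <- ev$onset + ev$duration
  bad <- which(ev$onset[-1] < ends[-nrow(ev)] - 1e-9)
  if (length(bad))
    stop(sprintf("overlapping %s events at onsets %g and %g", what,
                 ev$onset[bad[1]], ev$onset[bad[1] + 1]))
  invisible(TRUE)
}

aEvents <- function(events) {
  ev <- events[events$label %in% c("A1", "A2", "A3"), , drop = FALSE]
  ev[order(ev$onset), , drop = FALSE]
}

#' Merge close phase-A events
#'
#' Successive A events separated by less than 2 s (strict) become one event
#' spanning both; applied iteratively to a fixed point, so chains of close
#' events cascade into a single interval. Idempotent.
#'
#' @param events annotation data frame (only A1/A2/A3 rows are used) or a
#'   data frame of A events.
#' @param gap merge threshold in seconds.
#' @return data frame of merged A events with label \code{"A"}.
#' @export
mergePhaseA <- function(events, gap = 2) {
  ev <- events
  if ("label" %in% names(ev) && !all(ev$label == "A"))
    ev <- aEvents(ev)
  ev <- ev[order(ev$onset), , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  onset <- ev$onset[1]; end <- ev$onset[1] + ev$duration[1]
  outOn <- numeric(0); outEnd <- numeric(0)
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev$onset[i] - end < gap) {          # strict "<": gap == 2 stays split
      end <- max(end, ev$onset[i] + ev$duration[i])
    } else {
      outOn <- c(outOn, onset); outEnd <- c(outEnd, end)
      onset <- ev$onset[i]; end <- ev$onset[i] + ev$duration[i]
    }
  }
  outOn <- c(outOn, onset); outEnd <- c(outEnd, end)
  data.frame(onset = outOn, duration = outEnd - outOn, label = "A",
             stringsAsFactors = FALSE)
}

#' Build CAP sequences from merged A events
#'
#' B phases are the inter-A intervals. A chain breaks when an inter-A gap
#' exceeds 60 s or a phase duration falls outside \[2, 60\] s; surviving
#' chains with at least three A phases become CAP sequences (the pattern
#' A-B-A-B-A at minimum). A sequence starts at its first A onset and ends at
#' the end of its terminal A. Isolated A phases are non-CAP and excluded.
#'
#' @param events merged A events (see \code{\link{mergePhaseA}}) or a raw
#'   annotation frame (merged internally).
#' @param minA minimum number of A phases per sequence.
#' @param phaseRange admissible phase duration range in seconds.
#' @param maxGap non-CAP threshold for the inter-A interval, seconds.
#' @return list of CAP sequences; each has \code{events} (data frame of
#'   alternating A/B phases), \code{n_A}, \code{start}, \code{end}.
#' @export
buildCapSequences <- function(events, minA = 3L, phaseRange = c(2, 60),
                              maxGap = 60) {
  A <- if (!nrow(events) || identical(unique(events$label), "A")) events
       else mergePhaseA(events)
  if (!nrow(A)) return(list())
  n <- nrow(A)
  ends <- A$onset + A$duration
  okA <- A$duration >= phaseRange[1] - 1e-9 & A$duration <= phaseRange[2] + 1e-9
  ## link i -> i+1 when the B phase between them is admissible
  linked <- logical(max(n - 1, 0))
  if (n > 1) for (i in seq_len(n - 1)) {
    b <- A$onset[i + 1] - ends[i]
    linked[i] <- okA[i] && okA[i + 1] && b >= phaseRange[1] - 1e-9 && b <= maxGap + 1e-9
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && linked[j]) j <- j + 1L
    if (j - i + 1L >= minA) {
      idx <- i:j
      evs <- data.frame(onset = numeric(0), duration = numeric(0),
                        label = character(0), stringsAsFactors = FALSE)
      for (k in idx) {
        evs <- rbind(evs, data.frame(onset = A$onset[k], duration = A$duration[k],
                                     label = "A", stringsAsFactors = FALSE))
        if (k < j)
          evs <- rbind(evs, data.frame(onset = ends[k],
                                       duration = A$onset[k + 1] - ends[k],
                                       label = "B", stringsAsFactors = FALSE))
      }
      out[[length(out) + 1L]] <- list(events = evs, n_A = length(idx),
                                      start = A$onset[i], end = ends[j])
    }
    i <- j + 1L
  }
  out
}

#' CAP parameters from sequences
#'
#' CAP time is the summed duration of all CAP sequences; CAP rate is CAP
#' time divided by total NREM time.
#'
#' @param sequences list from \code{\link{buildCapSequences}}.
#' @param nremTime total NREM sleep time in minutes.
#' @return list with \code{cap_time} and \code{nrem_time} (minutes) and
#'   \code{cap_rate}.
#' @export
computeCapParameters <- function(sequences, nremTime) {
  if (nremTime <= 0) stop("nremTime must be positive")
  capTime <- sum(vapply(sequences, function(s) s$end - s$start, 0.0)) / 60
  if (capTime > nremTime + 1e-9)
    stop("CAP time exceeds NREM time: inconsistent annotations")
  list(cap_time = capTime, nrem_time = nremTime, cap_rate = capTime / nremTime)
}

#' CAP rate from already-summed times
#'
#' Convenience for the bookkeeping identity \code{cap_rate = cap_time /
#' nrem_time}, as used in clinical microstructure tables.
#'
#' @param capTime CAP time in minutes.
#' @param nremTime NREM time in minutes.
#' @return the CAP rate.
#' @export
capRate <- function(capTime, nremTime) {
  if (nremTime <= 0) stop("nremTime must be positive")
  if (capTime > nremTime) stop("CAP time exceeds NREM time")
  capTime / nremTime
}

nremIntervalsFrom <- function(events, span) {
  st <- events[events$label %in% c("NREM1", "NREM2", "NREM3"), , drop = FALSE]
  if (!nrow(st)) return(data.frame(onset = span[1], end = span[2]))
  st <- st[order(st$onset), ]
  onset <- st$onset; end <- st$onset + st$duration
  outOn <- onset[1]; outEnd <- end[1]
  res <- data.frame(onset = numeric(0), end = numeric(0))
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= outEnd + 1e-9) outEnd <- max(outEnd, end[i])
    else { res <- rbind(res, data.frame(onset = outOn, end = outEnd))
           outOn <- onset[i]; outEnd <- end[i] }
  }
  rbind(res, data.frame(onset = outOn, end = outEnd))
}

tileInterval <- function(from, to, len) {
  n <- floor((to - from) / len + 1e-9)
  if (n < 1) return(numeric(0))
  from + len * (0:(n - 1))
}

#' Label NREM time and cut it into fixed-length epochs
#'
#' Merged phase-A intervals are class A; all remaining NREM time is class B
#' (the standard shortcut for the classification task). Each labeled
#' interval is tiled with non-overlapping windows of \code{epochLen} seconds
#' starting at the interval onset; trailing partial windows are dropped, and
#' REM/wake time contributes nothing.
#'
#' @param channels list of \linkS4class{EEGTimeSeries}, all at the same
#'   rate.
#' @param events annotation data frame (A events and, optionally,
#'   sleep-stage events; without stage events the whole recording counts as
#'   NREM).
#' @param epochLen epoch length in seconds (1 or 2).
#' @param subject subject id stored with every epoch.
#' @return an \linkS4class{EpochSet}.
#' @export
labelAndSegment <- function(channels, events, epochLen = 2, subject = "s1") {
  if (!epochLen %in% c(1, 2)) stop("epochLen must be 1 or 2 seconds")
  if (is(channels, "EEGTimeSeries")) channels <- list(channels)
  fs <- channels[[1]]@fs
  if (!all(vapply(channels, function(ch) ch@fs, 0.0) == fs))
    stop("all channels must share one sampling rate")
  span <- c(0, length(channels[[1]]@samples) / fs)
  nrem <- nremIntervalsFrom(events, span)
  A <- mergePhaseA(events)
  if (nrow(A) && (min(A$onset) < span[1] - 1e-9 ||
                  max(A$onset + A$duration) > span[2] + 1e-9))
    stop("annotation events extend beyond the recording span")

  starts <- numeric(0); labs <- character(0)
  for (i in seq_len(nrow(nrem))) {
    lo <- nrem$onset[i]; hi <- nrem$end[i]
    Ain <- A[A$onset < hi & A$onset + A$duration > lo, , drop = FALSE]
    cur <- lo
    segs <- data.frame(from = numeric(0), to = numeric(0), lab = character(0))
    for (j in seq_len(nrow(Ain))) {
      a0 <- max(Ain$onset[j], lo); a1 <- min(Ain$onset[j] + Ain$duration[j], hi)
      if (a0 > cur)
        segs <- rbind(segs, data.frame(from = cur, to = a0, lab = "B"))
      segs <- rbind(segs, data.frame(from = a0, to = a1, lab = "A"))
      cur <- a1
    }
    if (cur < hi) segs <- rbind(segs, data.frame(from = cur, to = hi, lab = "B"))
    for (j in seq_len(nrow(segs))) {
      ts <- tileInterval(segs$from[j], segs$to[j], epochLen)
      starts <- c(starts, ts)
      labs <- c(labs, rep(segs$lab[j], length(ts)))
    }
  }
  nSamp <- as.integer(round(epochLen * fs))
  keep <- round(starts * fs) + nSamp <= length(channels[[1]]@samples)
  starts <- starts[keep]; labs <- labs[keep]
  dat <- array(0, dim = c(length(starts), nSamp, length(channels)))
  chNames <- vapply(channels, function(ch) ch@label, "")
  chNames[is.na(chNames)] <- paste0("ch", which(is.na(chNames)))
  dimnames(dat) <- list(NULL, NULL, chNames)
  for (ci in seq_along(channels)) {
    v <- channels[[ci]]@samples
    for (ei in seq_along(starts)) {
      i0 <- as.integer(round(starts[ei] * fs))
      dat[ei, , ci] <- v[(i0 + 1L):(i0 + nSamp)]
    }
  }
  new("EpochSet", data = dat,
      labels = factor(labs, levels = c("A", "B")),
      epochLen = epochLen, fs = fs,
      subject = rep(subject, length(starts)))
}

#' Balance classes by random undersampling
#'
#' The majority class is undersampled without replacement to the minority
#' count; deterministic for a given seed.
#'
#' @param e an \linkS4class{EpochSet} containing both classes.
#' @param seed integer RNG seed.
#' @return balanced \linkS4class{EpochSet}.
#' @export
balanceClasses <- function(e, seed = 1L) {
  stopifnot(is(e, "EpochSet"))
  nA <- sum(e@labels == "A"); nB <- sum(e@labels == "B")
  if (nA == 0 || nB == 0) stop("both classes must be present to balance")
  if (nA == nB) return(e)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  maj <- if (nA > nB) "A" else "B"
  majIdx <- which(e@labels == maj)
  keep <- sort(c(which(e@labels != maj), sample(majIdx, min(nA, nB))))
  subsetEpochs(e, keep)
}

subsetEpochs <- function(e, idx) {
  new("EpochSet", data = e@data[idx, , , drop = FALSE],
      labels = factor(as.character(e@labels[idx]), levels = c("A", "B")),
      epochLen = e@epochLen, fs = e@fs, subject = e@subject[idx])
}
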