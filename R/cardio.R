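## R-peak detection and R-R series handling. The detector follows the
## classic Pan-Tompkins stages: 5-15 Hz bandpass, five-point derivative,
## squaring, 150 ms moving-window integration, then adaptive dual thresholds
## with a 200 ms refractory period and a search-back pass; each accepted
## fiducial is finally localized to the signal maximum within +/- 50 ms.

#' Construct an RRSeries
#'
#' @param rpeakTimes strictly increasing R-peak times in seconds.
#' @return an [RRSeries-class]; intervals are the successive differences
#'   in milliseconds.
#' @export
rrSeries <- function(rpeakTimes) {
  rpeakTimes <- as.numeric(rpeakTimes)
  new("RRSeries", rpeakTimes = rpeakTimes,
      rrIntervals = if (length(rpeakTimes) > 1) diff(rpeakTimes) * 1000
                    else numeric(0))
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' @param ecg highpass-filtered ECG samples.
#' @param fs sampling rate in Hz (>= 100).
#' @return an [RRSeries-class]; empty when the signal is flat.
#' @export
detectRPeaks <- function(ecg, fs) {
  stopifnot(fs >= 100)
  if (length(ecg) < 10 * fs) stop("signal shorter than 10 s")
  if (var(ecg) == 0) return(rrSeries(numeric(0)))

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, ecg))
  der <- as.numeric(stats::filter(filt, c(-1, -2, 0, 2, 1) / 8, sides = 2))
  der[is.na(der)] <- 0
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate fiducials: local maxima of the integrated signal, consolidated
  # by amplitude-ordered suppression within the refractory distance so minor
  # ripples on a QRS energy bump cannot pre-empt its true maximum
  d <- diff(mwi)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(rrSeries(numeric(0)))
  ord <- cand[order(mwi[cand], decreasing = TRUE)]
  sel <- logical(length(mwi))
  blocked <- logical(length(mwi))
  refrI <- as.integer(round(0.2 * fs))
  for (cIdx in ord) {
    if (blocked[cIdx]) next
    sel[cIdx] <- TRUE
    blocked[max(1L, cIdx - refrI):min(length(mwi), cIdx + refrI)] <- TRUE
  }
  cand <- which(sel)

  init <- mwi[seq_len(min(length(mwi), 2L * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- npki + 0.25 * (spki - npki)
  refr <- 0.2 * fs
  accepted <- integer(0)
  rrBuf <- numeric(0)
  lastAcc <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    cIdx <- cand[i]
    pk <- mwi[cIdx]
    if (pk > thr1 && (cIdx - lastAcc) > refr) {
      accepted <- c(accepted, cIdx)
      spki <- 0.125 * pk + 0.875 * spki
      if (length(accepted) > 1) {
        rrBuf <- c(rrBuf, cIdx - lastAcc)
        if (length(rrBuf) > 8) rrBuf <- tail(rrBuf, 8)
      }
      lastAcc <- cIdx
    } else if ((cIdx - lastAcc) > refr) {
      npki <- 0.125 * pk + 0.875 * npki
      # search-back: if no beat for 1.66x the running RR average, re-admit
      # the largest skipped candidate above the lower threshold
      if (length(rrBuf) >= 2 && (cIdx - lastAcc) > 1.66 * mean(rrBuf)) {
        win <- cand[cand > lastAcc + refr & cand <= cIdx]
        if (length(win)) {
          best <- win[which.max(mwi[win])]
          if (mwi[best] > 0.5 * thr1) {
            accepted <- c(accepted, best)
            spki <- 0.25 * mwi[best] + 0.75 * spki
            rrBuf <- c(rrBuf, best - lastAcc)
            if (length(rrBuf) > 8) rrBuf <- tail(rrBuf, 8)
            lastAcc <- best
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
    i <- i + 1L
  }
  if (!length(accepted)) return(rrSeries(numeric(0)))

  # localize each fiducial to the raw-signal maximum within +/- 50 ms
  half <- round(0.05 * fs)
  n <- length(ecg)
  peaks <- vapply(accepted, function(cIdx) {
    a <- max(1L, cIdx - half); b <- min(n, cIdx + half)
    as.integer(a + which.max(ecg[a:b]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # drop refinements that collapsed inside the refractory window
  if (length(peaks) > 1) {
    keep <- logical(length(peaks)); keep[1] <- TRUE
    last <- peaks[1]
    for (j in 2:length(peaks)) {
      if (peaks[j] - last > refr) { keep[j] <- TRUE; last <- peaks[j] }
      else if (ecg[peaks[j]] > ecg[last]) {
        keep[which(peaks == last)] <- FALSE
        keep[j] <- TRUE; last <- peaks[j]
      }
    }
    peaks <- peaks[keep]
  }
  rrSeries((peaks - 1) / fs)
}

#' Slice an RRSeries to the intervals terminating in a window
#'
#' Returns the sub-series of intervals whose terminating peak lies in the
#' half-open window `[t0, t1)`.
#'
#' @param series an [RRSeries-class].
#' @param t0,t1 window bounds in seconds, `t0 < t1`.
#' @return list with `rr` (interval vector, ms) and `peaks` (terminating
#'   peak times, s).
#' @export
rrInWindow <- function(series, t0, t1) {
  stopifnot(t0 < t1)
  tp <- series@rpeakTimes
  if (length(tp) < 2) return(list(rr = numeric(0), peaks = numeric(0)))
  term <- tp[-1]
  sel <- term >= t0 & term < t1
  list(rr = series@rrIntervals[sel], peaks = term[sel])
}

#' Drop physiologically implausible R-R intervals
#'
#' Intervals outside `[300, 2000]` ms are removed before feature
#' computation, mirroring the physiological-plausibility screening applied
#' to the raw channels.
#'
#' @param rr interval vector in ms.
#' @param lo,hi plausibility bounds in ms.
#' @return filtered interval vector.
#' @export
filterEctopic <- function(rr, lo = 300, hi = 2000) rr[rr >= lo & rr <= hi]
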