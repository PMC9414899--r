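## Stream cleaning and alignment: band-limited resampling to nominal rates,
## zero-phase highpass filtering (5th-order Butterworth, 1 Hz cutoff, applied
## to accelerometer and ECG), cross-correlation time synchronization on the
## ECG channels, and the per-epoch physiological validity screen.

#' Highpass filter specification
#'
#' Fifth-order Butterworth highpass at 1 Hz by default, applied
#' forward-backward (zero phase) so R-peak timing is preserved.
#'
#' @param order filter order.
#' @param cutoffHz cutoff frequency in Hz.
#' @return a list with class `"FilterSpec"`.
#' @export
filterSpec <- function(order = 5, cutoffHz = 1.0) {
  structure(list(kind = "highpass", order = order, cutoffHz = cutoffHz,
                 design = "butterworth"), class = "FilterSpec")
}

#' Resample a channel to a new rate
#'
#' Band-limited rational resampling (polyphase FIR). The output length is
#' `round(n * fsOut / fsIn)`.
#'
#' @param samples numeric sample vector.
#' @param fsIn,fsOut input/output sampling rates in Hz.
#' @return resampled numeric vector.
#' @export
resampleChannel <- function(samples, fsIn, fsOut) {
  if (length(samples) == 0) stop("empty input")
  stopifnot(fsIn > 0, fsOut > 0)
  if (fsIn == fsOut) return(samples)
  n <- length(samples)
  nOut <- round(n * fsOut / fsIn)
  # smallest integer ratio p/q = fsOut/fsIn
  r <- .ratApprox(fsOut / fsIn)
  # edge-pad (odd reflection) so the polyphase FIR transient falls outside
  pad <- min(n - 1L, 64L)
  mu <- mean(samples)
  x <- samples - mu   # the FIR passband ripple must not touch the DC level
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::resample(c(left, x, right), r$p, r$q) + mu
  skip <- round(pad * r$p / r$q)
  y <- y[(skip + 1L):length(y)]
  if (length(y) >= nOut) y[seq_len(nOut)]
  else c(y, rep(y[length(y)], nOut - length(y)))
}

.ratApprox <- function(x, maxDen = 4096L) {
  # continued-fraction rational approximation
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > maxDen || abs(p / q - x) < 1e-12) {
      if (q > maxDen) { p <- p1; q <- q1 }
      return(list(p = as.integer(p), q = as.integer(q)))
    }
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    if (abs(r - a) < 1e-15) return(list(p = as.integer(p), q = as.integer(q)))
    r <- 1 / (r - a)
  }
}

## Butterworth highpass as cascaded second-order sections (bilinear
## transform of the analog prototype, prewarped). A cutoff far below the
## Nyquist rate makes the single transfer-function form ill-conditioned;
## biquad cascades keep the response accurate to machine precision.
.butterHpSos <- function(order, cutoffHz, fs) {
  K <- 1 / tan(pi * cutoffHz / fs)
  k <- seq_len(order)
  ang <- pi * (2 * k + order - 1) / (2 * order)
  poles <- exp(1i * ang)
  sections <- list()
  used <- logical(order)
  for (i in seq_len(order)) {
    if (used[i]) next
    if (abs(Im(poles[i])) < 1e-12) {       # real pole: first-order section
      sections[[length(sections) + 1L]] <-
        list(b = c(K, -K) / (K + 1), a = c(1, (1 - K) / (K + 1)))
      used[i] <- TRUE
    } else {                               # conjugate pair: biquad
      beta <- -2 * Re(poles[i])
      d0 <- K^2 + beta * K + 1
      sections[[length(sections) + 1L]] <-
        list(b = c(K^2, -2 * K^2, K^2) / d0,
             a = c(1, (2 - 2 * K^2) / d0, (K^2 - beta * K + 1) / d0))
      j <- which(!used & abs(poles - Conj(poles[i])) < 1e-9)[1]
      used[c(i, j)] <- TRUE
    }
  }
  sections
}

#' Zero-phase highpass filter
#'
#' Applies the Butterworth highpass of `spec` forward and backward
#' (zero phase), as a cascade of second-order sections, removing DC and
#' slow drift without phase shift.
#'
#' @param samples numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param spec a [filterSpec()].
#' @return filtered numeric vector of the same length.
#' @export
highpassFilter <- function(samples, fs, spec = filterSpec()) {
  if (spec$cutoffHz >= fs / 2) stop("cutoff must be below the Nyquist rate")
  if (length(samples) <= 3 * (spec$order + 1))
    stop("signal shorter than the filter warm-up length")
  # odd-reflection padding spanning several cutoff time constants keeps the
  # forward-backward transient out of the returned samples
  n <- length(samples)
  x <- samples - mean(samples)   # remove DC up front; the filter kills the rest
  pad <- min(n - 1L, as.integer(ceiling(10 * fs / spec$cutoffHz)))
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  sos <- .butterHpSos(spec$order, spec$cutoffHz, fs)
  y <- rev(.sosForward(rev(.sosForward(c(left, x, right), sos)), sos))
  y[pad + seq_len(n)]
}

## single forward pass through the biquad cascade, zero initial conditions
.sosForward <- function(x, sections) {
  for (s in sections) {
    nb <- length(s$b)
    u <- as.numeric(stats::filter(c(numeric(nb - 1L), x), s$b,
                                  sides = 1))[nb - 1L + seq_along(x)]
    x <- as.numeric(stats::filter(u, -s$a[-1], method = "recursive"))
  }
  x
}

#' Estimate the lag between two ECG streams by cross-correlation
#'
#' Both signals are resampled to a common rate and the lag maximizing their
#' normalized cross-correlation within `maxLagS` is returned. Positive lag
#' means the target starts later than the reference.
#'
#' @param refEcg,targetEcg numeric ECG sample vectors (highpass-filtered).
#' @param refFs,targetFs their sampling rates (Hz).
#' @param maxLagS search half-window in seconds.
#' @param commonRateHz analysis rate both signals are brought to.
#' @return estimated lag in seconds.
#' @export
synchronizeByEcg <- function(refEcg, refFs, targetEcg, targetFs,
                             maxLagS = 300, commonRateHz = 128) {
  if (length(refEcg) / refFs < 60 || length(targetEcg) / targetFs < 60)
    stop("both signals must span at least 60 s")
  a <- resampleChannel(refEcg, refFs, commonRateHz)
  b <- resampleChannel(targetEcg, targetFs, commonRateHz)
  if (sd(a) == 0 || sd(b) == 0)
    stop("synchronization failure: flat ECG signal")
  a <- (a - mean(a)) / sd(a)
  b <- (b - mean(b)) / sd(b)
  n <- max(length(a), length(b))
  nf <- stats::nextn(2L * n, 2)
  fa <- fft(c(a, numeric(nf - length(a))))
  fb <- fft(c(b, numeric(nf - length(b))))
  # cc[k+1] = sum_m b[m + k] * a[m]; the peak sits at k = d when the target
  # is the reference delayed by d samples (target starts later: positive lag)
  cc <- Re(fft(fb * Conj(fa), inverse = TRUE)) / nf
  maxLag <- min(round(maxLagS * commonRateHz), n - 1L)
  lags <- c(0:maxLag, -(maxLag:1))
  vals <- cc[c(seq_len(maxLag + 1L), nf - (maxLag:1) + 1L)]
  lags[which.max(vals)] / commonRateHz
}

#' Per-epoch physiological validity screen
#'
#' An epoch is invalid when its minimum SpO2 is below 50% or its minimum
#' heart rate is below 40 bpm ("less than" is strict: 50.0 / 40.0 pass);
#' such values are physiologically unrealistic and indicate noisy sensor
#' contact. Missing inputs mark the epoch invalid with reason `"missing"`.
#'
#' @param epochSpo2Min minimum SpO2 (%) in the epoch.
#' @param epochHrMin minimum heart rate (bpm) in the epoch.
#' @param spo2Threshold,hrThreshold screen thresholds.
#' @return list with `valid` (logical) and `reason` (character or NA).
#' @export
validityScreen <- function(epochSpo2Min, epochHrMin,
                           spo2Threshold = 50, hrThreshold = 40) {
  if (is.null(epochSpo2Min) || is.null(epochHrMin) ||
      is.na(epochSpo2Min) || is.na(epochHrMin))
    return(list(valid = FALSE, reason = "missing"))
  if (epochSpo2Min < spo2Threshold)
    return(list(valid = FALSE, reason = "spo2_min_below_50"))
  if (epochHrMin < hrThreshold)
    return(list(valid = FALSE, reason = "hr_min_below_40"))
  list(valid = TRUE, reason = NA_character_)
}
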