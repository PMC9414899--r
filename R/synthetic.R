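## Synthetic overnight recordings with known-by-construction physiology.
## Sleep stages follow a first-order Markov chain at 30-s resolution; ECG is
## a fixed QRS template placed at stochastic R-times whose mean and
## variability depend on the current stage; SpO2, acceleration and skin
## temperature carry stage-dependent events (desaturations, movement bursts,
## distal warming during sleep). Ground truth (hypnogram, R-peak times,
## injected sync offsets) is retained so every downstream stage is testable.

.defaultTransition <- function() {
  tm <- rbind(
    Wake = c(0.920, 0.060, 0.010, 0.005, 0.005),
    N1   = c(0.050, 0.700, 0.220, 0.010, 0.020),
    N2   = c(0.010, 0.030, 0.900, 0.035, 0.025),
    N3   = c(0.005, 0.005, 0.060, 0.920, 0.010),
    REM  = c(0.020, 0.030, 0.040, 0.005, 0.905))
  colnames(tm) <- STAGES5
  tm
}

#' Construct a synthetic-subject configuration
#'
#' Defaults describe a plausible overnight inpatient recording: 8 h duration,
#' stage-dependent heart rate falling from Wake (78 bpm) to N3 (56 bpm),
#' higher vagally mediated (HF) variability share in deep sleep, ~6
#' desaturation events/h of 6 percentage points, movement concentrated in
#' Wake, and a 1.5 deg C distal temperature rise during sleep.
#'
#' @param subjectId identifier.
#' @param durationH duration in hours.
#' @param stageTransition 5x5 row-stochastic matrix (rows/cols
#'   Wake,N1,N2,N3,REM) at 30-s steps.
#' @param stageHrMean,stageHrSdnn,stageHfLfBalance named per-stage vectors
#'   (bpm, ms, unitless HF share in \[0,1\]).
#' @param desatRate,desatDepth,desatDurationS desaturation event process.
#' @param movementBurstRate bursts/hour per stage.
#' @param tempBaselineChest,tempBaselineLimb,dpgSleepShift temperatures (deg C).
#' @param subjectOffsetScale subject baseline-offset scale (0 = none).
#' @param noiseSd named per-channel additive noise SD.
#' @param psgEcgOffsetS offset (s) for the duplicated reference ECG.
#' @param seed integer seed.
#' @return a validated [SyntheticSubjectConfig-class] object.
#' @export
#' @examples
#' cfg <- syntheticSubjectConfig("s1", durationH = 1, seed = 7)
#' hyp <- generateHypnogram(cfg)
#' table(epochLabels(hyp))
syntheticSubjectConfig <- function(subjectId = "s1",
    durationH = 8,
    stageTransition = .defaultTransition(),
    stageHrMean = c(Wake = 78, N1 = 68, N2 = 62, N3 = 56, REM = 72),
    stageHrSdnn = c(Wake = 50, N1 = 45, N2 = 40, N3 = 25, REM = 55),
    stageHfLfBalance = c(Wake = 0.30, N1 = 0.45, N2 = 0.60, N3 = 0.75,
                         REM = 0.25),
    desatRate = 6, desatDepth = 6, desatDurationS = 25,
    movementBurstRate = c(Wake = 60, N1 = 8, N2 = 3, N3 = 1, REM = 2),
    tempBaselineChest = 35.5, tempBaselineLimb = 33.5, dpgSleepShift = 1.5,
    subjectOffsetScale = 0,
    noiseSd = c(ecg = 0.03, acc_x = 0.02, acc_y = 0.02, acc_z = 0.02,
                spo2 = 0.3, temp_chest = 0.05, temp_limb = 0.05,
                hr_device = 0.5),
    psgEcgOffsetS = 0, seed = 1L) {
  new("SyntheticSubjectConfig", subjectId = subjectId, durationH = durationH,
      stageTransition = stageTransition,
      stageHrMean = stageHrMean[STAGES5], stageHrSdnn = stageHrSdnn[STAGES5],
      stageHfLfBalance = stageHfLfBalance[STAGES5],
      desatRate = desatRate, desatDepth = desatDepth,
      desatDurationS = desatDurationS,
      movementBurstRate = movementBurstRate[STAGES5],
      tempBaselineChest = tempBaselineChest,
      tempBaselineLimb = tempBaselineLimb, dpgSleepShift = dpgSleepShift,
      subjectOffsetScale = subjectOffsetScale, noiseSd = noiseSd,
      psgEcgOffsetS = psgEcgOffsetS, seed = as.integer(seed))
}

#' Simulate a hypnogram from the stage-transition Markov chain
#'
#' Draws `durationH * 120` epoch labels from a first-order Markov chain at
#' 30-s steps, starting in Wake. Reproducible given `config@seed`.
#'
#' @param config a [SyntheticSubjectConfig-class].
#' @return a [Hypnogram-class].
#' @export
generateHypnogram <- function(config) {
  validObject(config)
  nEp <- round(config@durationH * 120)
  tm <- config@stageTransition
  withr::local_seed(config@seed)
  lab <- integer(nEp)
  state <- 1L  # recordings begin at bedtime, i.e. Wake
  for (k in seq_len(nEp)) {
    lab[k] <- state
    state <- sample.int(5L, 1L, prob = tm[state, ])
  }
  new("Hypnogram", labels = factor(STAGES5[lab], levels = STAGES5),
      epochLengthS = 30, startTime = 0)
}

## Subject-specific additive baselines, drawn once per subject from the
## config seed so recordings are reproducible.
.subjectOffsets <- function(config) {
  withr::local_seed(config@seed + 77L)
  s <- config@subjectOffsetScale
  list(hr = s * rnorm(1, 0, 8),       # bpm
       spo2 = -abs(s * rnorm(1, 0, 1.2)),  # saturation only drifts down
       temp = s * rnorm(1, 0, 0.8))   # deg C, both sites
}

## QRS-complex template sampled at `fs`: dominant positive R wave with small
## Q/S deflections and a low T wave. Only R-time geometry matters downstream.
.qrsTemplate <- function(fs) {
  t <- seq(-0.08, 0.35, by = 1 / fs)
  w <- 1.2 * exp(-t^2 / (2 * 0.011^2)) -
       0.25 * exp(-(t + 0.028)^2 / (2 * 0.008^2)) -
       0.30 * exp(-(t - 0.035)^2 / (2 * 0.009^2)) +
       0.15 * exp(-(t - 0.22)^2 / (2 * 0.045^2))
  list(w = w, center = which.max(w))
}

## Stage-dependent R-time point process: mean interval 60000/HR ms, with a
## two-band (0.1 Hz LF / 0.25 Hz HF) oscillatory modulation carrying 85% of
## the stage SDNN variance split by stageHfLfBalance, plus white jitter.
.simulateRtimes <- function(config, hypnogram, off) {
  durS <- config@durationH * 3600
  labs <- as.integer(hypnogram@labels)
  hr <- config@stageHrMean + off$hr
  sdnn <- config@stageHrSdnn
  hfShare <- config@stageHfLfBalance
  phiLf <- runif(1, 0, 2 * pi); phiHf <- runif(1, 0, 2 * pi)
  nMax <- ceiling(durS * max(hr) / 60) + 16L
  tp <- numeric(nMax)
  t <- 0.3; i <- 0L
  while (t < durS) {
    i <- i + 1L
    tp[i] <- t
    st <- labs[min(length(labs), floor(t / 30) + 1L)]
    aLf <- sdnn[st] * sqrt(2 * 0.85 * (1 - hfShare[st]))
    aHf <- sdnn[st] * sqrt(2 * 0.85 * hfShare[st])
    modMs <- aLf * sin(2 * pi * 0.1 * t + phiLf) +
             aHf * sin(2 * pi * 0.25 * t + phiHf) +
             rnorm(1, 0, sqrt(0.15) * sdnn[st])
    rr <- 60 / hr[st] + modMs / 1000
    t <- t + max(rr, 0.3)  # RR intervals always positive
  }
  tp[seq_len(i)]
}

.renderEcg <- function(rtimes, durS, fs, noiseSd) {
  n <- round(durS * fs)
  ecg <- rnorm(n, 0, noiseSd)
  tpl <- .qrsTemplate(fs)
  idx0 <- round(rtimes * fs) + 1L - (tpl$center - 1L)
  for (k in seq_along(tpl$w)) {
    ii <- idx0 + (k - 1L)
    ok <- ii >= 1L & ii <= n
    ecg[ii[ok]] <- ecg[ii[ok]] + tpl$w[k]
  }
  ecg
}

.trapezoidProfile <- function(nSamp) {
  # ramp down 25%, plateau 50%, ramp up 25% of the event duration
  nr <- max(1L, round(nSamp * 0.25))
  np <- max(0L, nSamp - 2L * nr)
  c(seq(0, 1, length.out = nr), rep(1, np), seq(1, 0, length.out = nr))
}

.simulateSpo2 <- function(config, durS, off) {
  fs <- CHANNEL_FS[["spo2"]]
  n <- round(durS * fs)
  base <- min(97 + off$spo2, 99.5)
  x <- rep(base, n)
  if (config@desatRate > 0) {
    t <- rexp(1, config@desatRate / 3600)
    while (t < durS) {
      prof <- .trapezoidProfile(round(config@desatDurationS * fs))
      i0 <- round(t * fs) + 1L
      ii <- i0:min(n, i0 + length(prof) - 1L)
      x[ii] <- x[ii] - config@desatDepth * prof[seq_along(ii)]
      t <- t + config@desatDurationS + rexp(1, config@desatRate / 3600)
    }
  }
  pmin(pmax(x + rnorm(n, 0, config@noiseSd[["spo2"]]), 0), 100)
}

.simulateAcc <- function(config, hypnogram, durS) {
  labs <- as.integer(hypnogram@labels)
  out <- list()
  gravity <- c(acc_x = 0.10, acc_y = 0.05, acc_z = 0.98)
  # movement bursts are drawn once (per epoch) and rendered on each axis
  nB <- rpois(length(labs), config@movementBurstRate[labs] / 120)
  starts <- lapply(seq_along(labs), function(k)
    if (nB[k] > 0) (k - 1) * 30 + runif(nB[k], 0, 28) else numeric(0))
  starts <- unlist(starts)
  for (ax in c("acc_x", "acc_y", "acc_z")) {
    fs <- CHANNEL_FS[[ax]]
    n <- round(durS * fs)
    x <- gravity[[ax]] + rnorm(n, 0, config@noiseSd[[ax]])
    for (s in starts) {
      ii <- (round(s * fs) + 1L):min(n, round((s + 2) * fs))
      x[ii] <- x[ii] + rnorm(length(ii), 0, 0.4)
    }
    out[[ax]] <- x
  }
  out
}

.simulateTemps <- function(config, hypnogram, durS, off) {
  n <- round(durS)
  labs <- as.integer(hypnogram@labels)
  sleepInd <- as.numeric(labs[pmin(length(labs), floor(seq_len(n) / 30) + 1L)] != 1L)
  # distal vasodilation follows sleep onset with a ~5 min smoothing window
  k <- rep(1 / 300, 300)
  sm <- as.numeric(stats::filter(c(rep(sleepInd[1], 299), sleepInd), k,
                                 sides = 1))[299 + seq_len(n)]
  drift <- 0.1 * sin(2 * pi * seq_len(n) / 7200)
  chest <- config@tempBaselineChest + off$temp + drift +
    rnorm(n, 0, config@noiseSd[["temp_chest"]])
  limb <- config@tempBaselineLimb + off$temp + drift +
    config@dpgSleepShift * sm + rnorm(n, 0, config@noiseSd[["temp_limb"]])
  list(temp_chest = pmin(pmax(chest, 20), 45),
       temp_limb = pmin(pmax(limb, 20), 45))
}

#' Simulate the multichannel recording for a hypnogram
#'
#' Renders all eight channels at their nominal rates (ECG 512 Hz, x/y
#' acceleration 52 Hz, z acceleration 416 Hz, SpO2 5 Hz, temperatures and
#' device heart rate 1 Hz) with stage-dependent physiology and retains the
#' true R-peak times.
#'
#' @param config a [SyntheticSubjectConfig-class].
#' @param hypnogram the [Hypnogram-class] to condition on; must match
#'   `config@durationH`.
#' @return a [SensorRecording-class].
#' @export
generateRecording <- function(config, hypnogram) {
  validObject(config); validObject(hypnogram)
  if (length(hypnogram@labels) != round(config@durationH * 120))
    stop("hypnogram length does not match config durationH")
  durS <- config@durationH * 3600
  off <- .subjectOffsets(config)
  withr::local_seed(config@seed + 1L)
  rt <- .simulateRtimes(config, hypnogram, off)
  ecg <- .renderEcg(rt, durS, CHANNEL_FS[["ecg"]], config@noiseSd[["ecg"]])
  spo2 <- .simulateSpo2(config, durS, off)
  acc <- .simulateAcc(config, hypnogram, durS)
  temps <- .simulateTemps(config, hypnogram, durS, off)
  hrInst <- 60 / diff(rt)
  hrDev <- approx(rt[-1], hrInst, xout = seq_len(round(durS)) - 0.5,
                  rule = 2)$y + rnorm(round(durS), 0,
                                      config@noiseSd[["hr_device"]])
  chans <- c(list(ecg = ecg), acc,
             list(spo2 = spo2, temp_chest = temps$temp_chest,
                  temp_limb = temps$temp_limb, hr_device = hrDev))
  new("SensorRecording", channels = chans[CHANNELS], fs = CHANNEL_FS,
      startTime = 0, groundTruthRpeaks = rt,
      groundTruthOffsetS = NA_real_)
}

#' Derive a time-shifted noisy copy of the ECG channel
#'
#' Emulates the reference polysomnograph's independently clocked ECG:
#' the recording's ECG delayed by `offsetS` seconds (zero-padded) with
#' independent additive noise at the given amplitude signal-to-noise ratio.
#' Positive `offsetS` means the copy starts later than the original.
#'
#' @param recording a [SensorRecording-class].
#' @param offsetS time offset in seconds; |offsetS| must be smaller than the
#'   recording duration.
#' @param snr amplitude SNR of the added noise; `Inf` adds none.
#' @return list with `ecg` (shifted samples), `fs`, and `offsetS` (the
#'   ground-truth lag).
#' @export
makePsgEcgCopy <- function(recording, offsetS, snr = Inf) {
  fs <- recording@fs[["ecg"]]
  x <- recording@channels$ecg
  if (abs(offsetS) >= length(x) / fs)
    stop("|offsetS| must be smaller than the recording duration")
  k <- round(offsetS * fs)
  y <- if (k >= 0) c(numeric(k), x[seq_len(length(x) - k)])
       else c(x[(-k + 1):length(x)], numeric(-k))
  if (is.finite(snr)) y <- y + rnorm(length(y), 0, sd(x) / snr)
  list(ecg = y, fs = fs, offsetS = k / fs)
}

#' Simulate a cohort of subjects around shared defaults
#'
#' Per-subject configurations are drawn around the defaults of
#' [syntheticSubjectConfig()]. `heterogeneity` scales both the additive
#' subject baseline offsets and per-subject perturbations of the
#' stage-dependent contrasts (stage heart-rate means, HF/LF balance,
#' movement rates and the sleep-related distal temperature shift), so at
#' `heterogeneity = 0` all subjects share identical physiology while at
#' high values the feature-to-stage mapping itself differs across subjects.
#'
#' @param nSubjects number of subjects (>= 1); the default cohort is nine
#'   usable subjects with about 5.4 h of data each.
#' @param heterogeneity non-negative scale of between-subject variation.
#' @param seed integer seed.
#' @param durationH per-subject duration in hours.
#' @param ... further arguments passed to [syntheticSubjectConfig()].
#' @return a list of `list(config, recording, hypnogram)` per subject.
#' @export
generateCohort <- function(nSubjects = 9, heterogeneity = 0, seed = 1L,
                           durationH = 5.4, ...) {
  stopifnot(nSubjects >= 1, heterogeneity >= 0)
  withr::local_seed(as.integer(seed))
  subSeeds <- sample.int(2^30, nSubjects)
  base <- syntheticSubjectConfig(durationH = durationH, ...)
  lapply(seq_len(nSubjects), function(i) {
    withr::local_seed(subSeeds[i])
    hrMean <- base@stageHrMean + heterogeneity * rnorm(5, 0, 4)
    hrMean <- pmax(hrMean, 45)
    bal <- pmin(pmax(base@stageHfLfBalance +
                       heterogeneity * rnorm(5, 0, 0.12), 0), 1)
    mov <- base@movementBurstRate *
      exp(heterogeneity * rnorm(5, 0, 0.4))
    dpg <- max(base@dpgSleepShift + heterogeneity * rnorm(1, 0, 0.5), 0)
    cfg <- syntheticSubjectConfig(
      subjectId = sprintf("s%02d", i), durationH = durationH,
      stageHrMean = setNames(hrMean, STAGES5),
      stageHfLfBalance = setNames(bal, STAGES5),
      movementBurstRate = setNames(mov, STAGES5),
      dpgSleepShift = dpg, subjectOffsetScale = heterogeneity,
      seed = subSeeds[i], ...)
    hyp <- generateHypnogram(cfg)
    list(config = cfg, recording = generateRecording(cfg, hyp),
         hypnogram = hyp)
  })
}

#' Inject validation artifacts into a synthetic recording
#'
#' `injectSpo2Dip` overwrites one epoch's SpO2 samples with a fixed value;
#' `injectBradycardia` replaces one epoch's ECG with beats at a slow fixed
#' rate (placed just inside the epoch boundaries so neighbouring epochs keep
#' plausible R-R intervals) and updates the stored ground-truth R-peak times
#' and device heart-rate channel. Both are used to exercise the
#' physiological validity screen.
#'
#' @param recording a [SensorRecording-class].
#' @param epochIndex 0-based epoch to corrupt.
#' @param value SpO2 value to write (default 45).
#' @param bpm heart rate of the injected slow rhythm (default 34).
#' @return the modified [SensorRecording-class].
#' @export
injectSpo2Dip <- function(recording, epochIndex, value = 45) {
  fs <- recording@fs[["spo2"]]
  ii <- (floor(30 * epochIndex * fs) + 1L):floor(30 * (epochIndex + 1) * fs)
  recording@channels$spo2[ii] <- value
  recording
}

#' @rdname injectSpo2Dip
#' @export
injectBradycardia <- function(recording, epochIndex, bpm = 34) {
  fs <- recording@fs[["ecg"]]
  t0 <- 30 * epochIndex; t1 <- t0 + 30
  # clear a short guard span past the epoch end so no original beat sits
  # within the refractory distance of the anchored final slow beat
  guard <- 0.35
  n <- length(recording@channels$ecg)
  ii <- (floor(t0 * fs) + 1L):min(n, floor((t1 + guard) * fs))
  noiseLevel <- mad(recording@channels$ecg)
  recording@channels$ecg[ii] <- rnorm(length(ii), 0, noiseLevel)
  # anchor the slow beat train at the epoch end so the interval crossing
  # into the next epoch stays short; the interval entering this epoch
  # terminates here and only affects the epoch being corrupted
  newT <- rev(seq(t1 - 0.05, t0 + 0.05, by = -60 / bpm))
  tpl <- .qrsTemplate(fs)
  idx0 <- round(newT * fs) + 1L - (tpl$center - 1L)
  n <- length(recording@channels$ecg)
  for (k in seq_along(tpl$w)) {
    jj <- idx0 + (k - 1L)
    ok <- jj >= 1L & jj <= n
    recording@channels$ecg[jj[ok]] <- recording@channels$ecg[jj[ok]] + tpl$w[k]
  }
  gt <- recording@groundTruthRpeaks
  if (length(gt))
    recording@groundTruthRpeaks <-
      sort(c(gt[gt < t0 | gt >= t1 + guard], newT))
  hr <- recording@channels$hr_device
  jj <- (floor(t0) + 1L):min(length(hr), floor(t1))
  recording@channels$hr_device[jj] <- bpm
  recording
}
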