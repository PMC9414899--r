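## Per-epoch feature extraction: 73 features over four sensor modalities
## (33 accelerometer, 19 ECG/HRV, 6 temperature, 15 oximetry), computed on
## non-overlapping 30-s epochs and paired with collapsed stage labels.

.ACC_STATS <- c("mean", "min", "max", "range", "iqr", "sd", "kurtosis",
                "rms", "variance")
.ACC_PAIRS <- c("xy", "xz", "yz")

featureNamesAcc <- function() {
  c(as.vector(t(outer(.ACC_STATS, c("x", "y", "z"),
                      function(s, a) paste0("acc_", s, "_", a)))),
    paste0("acc_rho_", .ACC_PAIRS), paste0("acc_p_", .ACC_PAIRS))
}

featureNamesEcg <- function() {
  c("hr_mean", "hr_min", "hr_max", "sdnn", "rmssd", "nn50", "nn20",
    "pnn50", "pnn20", "vlf_power", "vlf_peak", "lf_power", "lf_peak",
    "hf_power", "hf_peak", "lf_hf_ratio", "rr_mean", "rr_min", "rr_max")
}

featureNamesTemp <- function() {
  c("dpg_mean", "dpg_min", "dpg_max", "dpg_range", "chest_mean", "limb_mean")
}

featureNamesSpo2 <- function() {
  c("spo2_mean", "spo2_min", "spo2_variance", "spo2_rho", "spo2_zc",
    "spo2_di", paste0("tsa", c(95, 90, 85, 80, 70)),
    paste0("odi", 2:5))
}

#' Canonical feature inventory
#'
#' The fixed, documented order of the 73 per-epoch features and their
#' sensor modalities (33 ACC, 19 ECG, 6 TEMP, 15 SPO2).
#'
#' @return data.frame with columns `feature` and `modality`.
#' @export
featureInventory <- function() {
  data.frame(
    feature = c(featureNamesAcc(), featureNamesEcg(), featureNamesTemp(),
                featureNamesSpo2()),
    modality = rep(c("ACC", "ECG", "TEMP", "SPO2"), c(33L, 19L, 6L, 15L)),
    stringsAsFactors = FALSE)
}

## population (n) conventions throughout, so hand oracles are exact
.popVar <- function(x) mean((x - mean(x))^2)
.popSd <- function(x) sqrt(.popVar(x))
.kurtosis <- function(x) {
  v <- .popVar(x)
  if (v == 0) return(0)           # undefined on a constant axis
  mean((x - mean(x))^4) / v^2     # Pearson kurtosis (3 for a Gaussian)
}

#' Segment a recording and hypnogram into 30-s epoch windows
#'
#' Half-open windows `[30k, 30(k+1))` from the shared start; a trailing
#' partial epoch is dropped. If the hypnogram is shorter than the recording
#' the overlap is used with a warning.
#'
#' @param recording a [SensorRecording-class].
#' @param hypnogram a [Hypnogram-class].
#' @return data.frame with `epoch_index` (0-based), `t0`, `t1`, `label5`.
#' @export
segmentEpochs <- function(recording, hypnogram) {
  durS <- length(recording@channels$ecg) / recording@fs[["ecg"]]
  nRec <- floor(durS / 30)
  nHyp <- length(hypnogram@labels)
  if (nHyp < nRec) {
    warning("hypnogram shorter than recording; truncating to overlap")
    nRec <- nHyp
  }
  k <- seq_len(nRec) - 1L
  data.frame(epoch_index = k, t0 = 30 * k, t1 = 30 * (k + 1),
             label5 = as.character(hypnogram@labels[k + 1L]),
             stringsAsFactors = FALSE)
}

.epochSlice <- function(x, fs, t0, t1) {
  i0 <- floor(t0 * fs) + 1L
  i1 <- min(length(x), floor(t1 * fs))
  if (i0 > i1) numeric(0) else x[i0:i1]
}

#' Accelerometer features for one epoch (33 values)
#'
#' Nine per-axis statistics (mean, min, max, range, IQR, SD, kurtosis, RMS,
#' variance; population conventions) plus pairwise Pearson correlations and
#' their p-values for (x,y), (x,z), (y,z). Axes must share a common 52 Hz
#' grid. Pairs involving a constant axis get rho 0 and p 1.
#'
#' @param x,y,z numeric axis vectors of equal length.
#' @return named numeric vector of length 33.
#' @export
accFeatures <- function(x, y, z) {
  axes <- list(x = x, y = y, z = z)
  stopifnot(length(unique(lengths(axes))) == 1, length(x) > 0)
  stats1 <- function(a) c(mean = mean(a), min = min(a), max = max(a),
                          range = max(a) - min(a),
                          iqr = unname(quantile(a, 0.75) - quantile(a, 0.25)),
                          sd = .popSd(a), kurtosis = .kurtosis(a),
                          rms = sqrt(mean(a^2)), variance = .popVar(a))
  per <- vapply(axes, stats1, numeric(9))
  pairs <- list(xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"))
  rho <- p <- numeric(3)
  for (i in seq_along(pairs)) {
    a <- axes[[pairs[[i]][1]]]; b <- axes[[pairs[[i]][2]]]
    if (.popVar(a) == 0 || .popVar(b) == 0) { rho[i] <- 0; p[i] <- 1 }
    else {
      ct <- suppressWarnings(cor.test(a, b, method = "pearson"))
      rho[i] <- unname(ct$estimate); p[i] <- ct$p.value
    }
  }
  setNames(c(as.vector(t(per)), rho, p), featureNamesAcc())
}

## One-sided FFT periodogram of the 4 Hz interpolated R-R tachogram,
## zero-padded to 4096 points. On a 30-s epoch the window only spans one
## VLF cycle, so the VLF features are near-degenerate; they are computed
## literally for completeness.
.rrSpectrum <- function(rr, peaks, t0, t1, fsInterp = 4, nPad = 4096) {
  grid <- seq(t0, t1 - 1 / fsInterp, by = 1 / fsInterp)
  tach <- approx(peaks, rr, xout = grid, rule = 2)$y
  tach <- tach - mean(tach)
  n <- length(tach)
  xf <- fft(c(tach, numeric(nPad - n)))
  nh <- floor(nPad / 2)
  freq <- (seq_len(nh) - 1) * fsInterp / nPad
  # one-sided periodogram, ms^2/Hz, normalized by true sample count
  psd <- (2 / (fsInterp * n)) * Mod(xf[seq_len(nh)])^2
  psd[1] <- psd[1] / 2
  list(freq = freq, psd = psd, df = fsInterp / nPad)
}

.bandFeatures <- function(spec, lo, hi) {
  sel <- spec$freq >= lo & spec$freq < hi
  if (!any(sel)) return(c(power = 0, peak = NA_real_))
  c(power = sum(spec$psd[sel]) * spec$df,
    peak = spec$freq[sel][which.max(spec$psd[sel])])
}

#' ECG/HRV features for one epoch (19 values)
#'
#' Time domain: HR mean/min/max (bpm, 60000/RR), SDNN, RMSSD, NN50/NN20
#' (counts of successive differences strictly above 50/20 ms), PNN50/PNN20
#' (as percentages of successive pairs), R-R mean/min/max (ms). Frequency
#' domain: FFT periodogram of the 4 Hz interpolated tachogram with band
#' powers and peak frequencies for VLF (0.0033-0.04 Hz), LF (0.04-0.15 Hz)
#' and HF (0.15-0.4 Hz), plus the LF/HF ratio.
#'
#' @param rr R-R intervals (ms) terminating in the epoch.
#' @param peaks terminating peak times (s), aligned with `rr`.
#' @param t0,t1 epoch window in seconds.
#' @return named numeric vector of length 19, or NULL when fewer than
#'   3 intervals are available (the epoch is then invalidated upstream).
#' @export
ecgFeatures <- function(rr, peaks, t0, t1) {
  if (length(rr) < 3) return(NULL)
  d <- diff(rr)
  nn50 <- sum(abs(d) > 50); nn20 <- sum(abs(d) > 20)
  spec <- .rrSpectrum(rr, peaks, t0, t1)
  vlf <- .bandFeatures(spec, 0.0033, 0.04)
  lf <- .bandFeatures(spec, 0.04, 0.15)
  hf <- .bandFeatures(spec, 0.15, 0.4)
  hr <- 60000 / rr
  setNames(c(mean(hr), min(hr), max(hr), .popSd(rr),
             sqrt(mean(d^2)), nn50, nn20,
             100 * nn50 / length(d), 100 * nn20 / length(d),
             vlf["power"], vlf["peak"], lf["power"], lf["peak"],
             hf["power"], hf["peak"],
             lf[["power"]] / (hf[["power"]] + 1e-12),
             mean(rr), min(rr), max(rr)),
           featureNamesEcg())
}

#' Skin-temperature features for one epoch (6 values)
#'
#' The distal-to-proximal gradient (DPG) is limb minus chest temperature on
#' the shared 1 Hz grid; reported are DPG mean/min/max/range plus the chest
#' and limb means.
#'
#' @param chest,limb numeric 1 Hz temperature vectors for the epoch.
#' @return named numeric vector of length 6, or NULL when a channel is
#'   missing/empty.
#' @export
tempFeatures <- function(chest, limb) {
  if (!length(chest) || !length(limb)) return(NULL)
  n <- min(length(chest), length(limb))
  dpg <- limb[seq_len(n)] - chest[seq_len(n)]
  setNames(c(mean(dpg), min(dpg), max(dpg), max(dpg) - min(dpg),
             mean(chest), mean(limb)), featureNamesTemp())
}

## Desaturation events: maximal sample runs at least 2 points (the
## shallowest reported threshold) below the previous epoch's mean; each
## event is classified by its depth, so ODI5 <= ODI4 <= ODI3 <= ODI2 holds
## by construction even when noise ripples inside a deep dip.
.odiEvents <- function(spo2, prevMean) {
  if (is.na(prevMean)) return(rep(0, 4))
  r <- rle((prevMean - spo2) >= 2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  depths <- prevMean - vapply(which(r$values), function(i)
    min(spo2[starts[i]:ends[i]]), numeric(1))
  vapply(2:5, function(th) sum(depths >= th), numeric(1))
}

#' Oximetry features for one epoch (15 values)
#'
#' Mean, min and variance of the epoch's SpO2; `rho` = lag-1
#' autocorrelation; `zc` = zero-crossing rate of the mean-removed signal
#' (crossings per second); `DI` = mean absolute difference between the
#' three successive 10-s window means; `TSAx` = seconds with SpO2 strictly
#' below x% (sample count / 5); `ODIx` = number of desaturation events —
#' maximal sample runs at least 2 points below the previous epoch's mean
#' SpO2 — whose depth reaches x percentage points (0 when no previous
#' valid epoch exists).
#'
#' @param spo2 5 Hz SpO2 samples of the epoch.
#' @param prevMean mean SpO2 of the most recent valid epoch, or NA.
#' @param fs sampling rate (Hz).
#' @return named numeric vector of length 15.
#' @export
spo2Features <- function(spo2, prevMean = NA_real_, fs = 5) {
  n <- length(spo2)
  stopifnot(n > 0)
  m <- mean(spo2)
  v <- .popVar(spo2)
  if (v == 0 || n < 2) rho <- 0
  else {
    a <- spo2[-n] - m; b <- spo2[-1] - m
    rho <- sum(a * b) / (n * v)
  }
  ctr <- spo2 - m
  zc <- sum(ctr[-n] * ctr[-1] < 0) / (n / fs)
  wlen <- 10 * fs
  nw <- floor(n / wlen)
  di <- if (nw >= 2) {
    wm <- vapply(seq_len(nw), function(i)
      mean(spo2[((i - 1) * wlen + 1):(i * wlen)]), numeric(1))
    mean(abs(diff(wm)))
  } else 0
  tsa <- vapply(c(95, 90, 85, 80, 70), function(th)
    sum(spo2 < th) / fs, numeric(1))
  odi <- .odiEvents(spo2, prevMean)
  setNames(c(m, min(spo2), v, rho, zc, di, tsa, odi), featureNamesSpo2())
}

#' Collapse 5-stage AASM labels to a coarser resolution
#'
#' 2-stage: Wake vs Sleep (N1+N2+N3+REM); 3-stage: Wake vs NREM (N1+N2+N3)
#' vs REM; 4-stage: Wake vs Light (N1+N2) vs Deep (N3) vs REM. Wake always
#' maps to Wake.
#'
#' @param labels factor/character over Wake,N1,N2,N3,REM.
#' @param nClasses 2, 3 or 4.
#' @return factor over the collapsed classes in canonical order.
#' @export
mapLabels <- function(labels, nClasses) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), STAGES5)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  map <- switch(as.character(nClasses),
    "2" = c(Wake = "Wake", N1 = "Sleep", N2 = "Sleep", N3 = "Sleep",
            REM = "Sleep"),
    "3" = c(Wake = "Wake", N1 = "NREM", N2 = "NREM", N3 = "NREM",
            REM = "REM"),
    "4" = c(Wake = "Wake", N1 = "Light", N2 = "Light", N3 = "Deep",
            REM = "REM"),
    stop("nClasses must be 2, 3 or 4"))
  factor(unname(map[labels]), levels = stageLevels(nClasses))
}

#' Canonical class levels per stage resolution
#' @param nClasses 2, 3, 4 or 5.
#' @return character vector of class levels.
#' @export
stageLevels <- function(nClasses) {
  switch(as.character(nClasses),
         "2" = c("Wake", "Sleep"),
         "3" = c("Wake", "NREM", "REM"),
         "4" = c("Wake", "Light", "Deep", "REM"),
         "5" = STAGES5,
         stop("nClasses must be 2, 3, 4 or 5"))
}

## Compute all features for one subject night. Returns the feature matrix,
## per-epoch validity and exclusion reasons.
.subjectFeatures <- function(recording, hypnogram, filter = filterSpec()) {
  segs <- segmentEpochs(recording, hypnogram)
  fsEcg <- recording@fs[["ecg"]]
  ecgF <- highpassFilter(recording@channels$ecg, fsEcg, filter)
  accx <- highpassFilter(recording@channels$acc_x,
                         recording@fs[["acc_x"]], filter)
  accy <- highpassFilter(recording@channels$acc_y,
                         recording@fs[["acc_y"]], filter)
  # z axis (416 Hz) is brought to the common 52 Hz grid before statistics
  accz <- resampleChannel(recording@channels$acc_z,
                          recording@fs[["acc_z"]], 52)
  accz <- highpassFilter(accz, 52, filter)
  series <- detectRPeaks(ecgF, fsEcg)
  inv <- featureInventory()
  X <- matrix(NA_real_, nrow = nrow(inv), ncol = nrow(segs),
              dimnames = list(inv$feature, NULL))
  valid <- logical(nrow(segs))
  reason <- rep(NA_character_, nrow(segs))
  prevValidSpo2Mean <- NA_real_
  for (j in seq_len(nrow(segs))) {
    t0 <- segs$t0[j]; t1 <- segs$t1[j]
    sp <- .epochSlice(recording@channels$spo2, recording@fs[["spo2"]], t0, t1)
    ch <- .epochSlice(recording@channels$temp_chest, 1, t0, t1)
    lb <- .epochSlice(recording@channels$temp_limb, 1, t0, t1)
    ax <- .epochSlice(accx, 52, t0, t1)
    ay <- .epochSlice(accy, 52, t0, t1)
    az <- .epochSlice(accz, 52, t0, t1)
    nax <- min(length(ax), length(ay), length(az))
    win <- rrInWindow(series, t0, t1)
    rr <- filterEctopic(win$rr)
    peaks <- win$peaks[win$rr >= 300 & win$rr <= 2000]
    if (!length(sp) || !length(ch) || !length(lb) || nax == 0) {
      reason[j] <- "missing"; next
    }
    # screen HR from detected R-R; fall back to the 1 Hz device channel
    hrMin <- if (length(rr) >= 2) 60000 / max(rr)
             else {
               dev <- .epochSlice(recording@channels$hr_device, 1, t0, t1)
               if (length(dev)) min(dev) else NA_real_
             }
    scr <- validityScreen(min(sp), hrMin)
    if (!scr$valid) { reason[j] <- scr$reason; next }
    ef <- ecgFeatures(rr, peaks, t0, t1)
    if (is.null(ef)) { reason[j] <- "too_few_beats"; next }
    X[, j] <- c(accFeatures(ax[seq_len(nax)], ay[seq_len(nax)],
                            az[seq_len(nax)]),
                ef, tempFeatures(ch, lb),
                spo2Features(sp, prevValidSpo2Mean))
    valid[j] <- TRUE
    prevValidSpo2Mean <- mean(sp)
  }
  list(segs = segs, X = X, valid = valid, reason = reason)
}

#' Build the per-epoch feature table for a cohort
#'
#' Runs preprocessing (filtering, z-axis decimation, R-peak detection),
#' computes the 73 features for every 30-s epoch, applies the physiological
#' validity screen and assembles the valid epochs into an
#' [EpochFeatureTable-class] (a `SummarizedExperiment` with features as
#' rows). Excluded epochs are tallied in `metadata(x)$excluded`.
#'
#' @param subjects list of `list(recording=, hypnogram=)` per subject, or a
#'   single such pair; elements may carry a `config` with the subject id.
#' @param subjectIds optional character ids (default s01, s02, ...).
#' @return an [EpochFeatureTable-class].
#' @export
buildFeatureTable <- function(subjects, subjectIds = NULL) {
  if (!is.null(subjects$recording)) subjects <- list(subjects)
  if (is.null(subjectIds))
    subjectIds <- vapply(seq_along(subjects), function(i) {
      cfg <- subjects[[i]]$config
      if (!is.null(cfg)) cfg@subjectId else sprintf("s%02d", i)
    }, character(1))
  mats <- list(); cds <- list(); excl <- list()
  for (i in seq_along(subjects)) {
    sf <- .subjectFeatures(subjects[[i]]$recording, subjects[[i]]$hypnogram)
    keep <- sf$valid
    mats[[i]] <- sf$X[, keep, drop = FALSE]
    if (!any(keep))
      message("subject ", subjectIds[i],
              ": no epochs passed the validity screen")
    lab5 <- sf$segs$label5
    cds[[i]] <- data.frame(
      subject_id = rep(subjectIds[i], sum(keep)),
      epoch_index = sf$segs$epoch_index[keep],
      label5 = factor(lab5[keep], levels = STAGES5),
      label2 = mapLabels(lab5[keep], 2), label3 = mapLabels(lab5[keep], 3),
      label4 = mapLabels(lab5[keep], 4), valid = rep(TRUE, sum(keep)),
      stringsAsFactors = FALSE)
    if (any(!keep))
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = subjectIds[i],
        epoch_index = sf$segs$epoch_index[!keep],
        reason = sf$reason[!keep], stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, mats)
  if (is.null(X) || ncol(X) == 0) stop("zero valid epochs")
  cd <- do.call(rbind, cds)
  colnames(X) <- sprintf("%s_e%04d", cd$subject_id, cd$epoch_index)
  rownames(cd) <- colnames(X)
  inv <- featureInventory()
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X),
    rowData = S4Vectors::DataFrame(inv),
    colData = S4Vectors::DataFrame(cd))
  S4Vectors::metadata(se)$excluded <-
    if (length(excl)) do.call(rbind, excl)
    else data.frame(subject_id = character(0), epoch_index = integer(0),
                    reason = character(0))
  new("EpochFeatureTable", se)
}

#' Export a feature table to CSV
#'
#' Writes epochs as rows with the fixed 73-column feature order followed by
#' the label columns, plus a JSON manifest mapping feature name to modality.
#'
#' @param table an [EpochFeatureTable-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFeatureTable <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  X <- t(SummarizedExperiment::assay(table, "features"))
  cd <- as.data.frame(SummarizedExperiment::colData(table))
  df <- cbind(cd[c("subject_id", "epoch_index")], as.data.frame(X),
              cd[c("label5", "label2", "label3", "label4")])
  fcsv <- file.path(dir, "features.csv")
  write.csv(df, fcsv, row.names = FALSE)
  man <- list(features = featureInventory(),
              n_epochs = ncol(table),
              excluded = S4Vectors::metadata(table)$excluded)
  fjson <- file.path(dir, "features_manifest.json")
  jsonlite::write_json(man, fjson, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(fcsv, fjson))
}
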