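#' @import methods
#' @importFrom stats approx cor cor.test dist fft mad median nextn predict
#'   quantile rexp rnorm rpois runif sd setNames var IQR
#' @importFrom utils head tail write.csv read.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Canonical stage vocabulary (AASM 30-s epoch scoring) and channel contract.
STAGES5 <- c("Wake", "N1", "N2", "N3", "REM")

CHANNELS <- c("ecg", "acc_x", "acc_y", "acc_z", "spo2",
              "temp_chest", "temp_limb", "hr_device")

CHANNEL_FS <- c(ecg = 512, acc_x = 52, acc_y = 52, acc_z = 416, spo2 = 5,
                temp_chest = 1, temp_limb = 1, hr_device = 1)

#' SyntheticSubjectConfig: parameters of one simulated overnight recording
#'
#' Holds everything needed to generate a reproducible synthetic night:
#' the 30-s sleep-stage Markov chain, stage-dependent cardiac parameters
#' (mean heart rate, interval variability and its split between the
#' low-frequency and high-frequency bands), oxygen-desaturation event
#' process, movement-burst rates, skin-temperature baselines and the
#' distal-temperature rise during sleep, per-channel noise levels, and a
#' subject-specific baseline-offset scale that drives between-subject
#' heterogeneity.
#'
#' @slot subjectId character scalar identifier.
#' @slot durationH recording duration in hours.
#' @slot stageTransition 5x5 row-stochastic matrix over
#'   Wake/N1/N2/N3/REM at 30-s steps.
#' @slot stageHrMean named numeric, mean heart rate (bpm) per stage.
#' @slot stageHrSdnn named numeric, R-R interval SD (ms) per stage.
#' @slot stageHfLfBalance named numeric in \[0,1\]: share of the oscillatory
#'   R-R modulation variance placed in the HF band (0.15-0.4 Hz) versus the
#'   LF band (0.04-0.15 Hz), per stage.
#' @slot desatRate desaturation events per hour.
#' @slot desatDepth desaturation depth in percentage points.
#' @slot desatDurationS desaturation event duration in seconds.
#' @slot movementBurstRate named numeric, movement bursts per hour per stage.
#' @slot tempBaselineChest,tempBaselineLimb baseline skin temperatures (deg C).
#' @slot dpgSleepShift distal temperature rise during sleep (deg C).
#' @slot subjectOffsetScale scale of subject-specific additive baseline
#'   offsets on HR, SpO2 and temperature (0 = homogeneous cohort).
#' @slot noiseSd named numeric, additive noise SD per channel.
#' @slot psgEcgOffsetS time offset (s) used when deriving a duplicated
#'   reference ECG channel for synchronization testing.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticSubjectConfig",
  representation(
    subjectId = "character",
    durationH = "numeric",
    stageTransition = "matrix",
    stageHrMean = "numeric",
    stageHrSdnn = "numeric",
    stageHfLfBalance = "numeric",
    desatRate = "numeric",
    desatDepth = "numeric",
    desatDurationS = "numeric",
    movementBurstRate = "numeric",
    tempBaselineChest = "numeric",
    tempBaselineLimb = "numeric",
    dpgSleepShift = "numeric",
    subjectOffsetScale = "numeric",
    noiseSd = "numeric",
    psgEcgOffsetS = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSubjectConfig", function(object) {
  msg <- character()
  tm <- object@stageTransition
  if (!all(dim(tm) == c(5L, 5L)))
    msg <- c(msg, "stageTransition must be a 5x5 matrix")
  else {
    if (any(tm < 0)) msg <- c(msg, "stageTransition entries must be >= 0")
    if (any(abs(rowSums(tm) - 1) > 1e-9))
      msg <- c(msg, "stageTransition rows must sum to 1 (tol 1e-9)")
  }
  if (object@durationH <= 0) msg <- c(msg, "durationH must be > 0")
  for (nm in c("stageHrMean", "stageHrSdnn", "stageHfLfBalance",
               "movementBurstRate"))
    if (!identical(names(slot(object, nm)), STAGES5))
      msg <- c(msg, sprintf("%s must be named by the five stages", nm))
  if (any(object@stageHrMean <= 40))
    msg <- c(msg, "stageHrMean must exceed 40 bpm")
  if (any(object@stageHfLfBalance < 0 | object@stageHfLfBalance > 1))
    msg <- c(msg, "stageHfLfBalance must lie in [0, 1]")
  if (object@desatRate < 0 || object@desatDepth < 0 ||
      object@desatDurationS < 0 || any(object@movementBurstRate < 0) ||
      any(object@stageHrSdnn < 0))
    msg <- c(msg, "rates, depths and durations must be >= 0")
  if (!all(CHANNELS %in% names(object@noiseSd)) || any(object@noiseSd < 0))
    msg <- c(msg, "noiseSd must be named by all channels and >= 0")
  if (length(msg)) msg else TRUE
})

#' Hypnogram: ordered 30-s epoch sleep-stage labels
#'
#' @slot labels factor over Wake/N1/N2/N3/REM, one per 30-s epoch.
#' @slot epochLengthS epoch length in seconds (fixed at 30).
#' @slot startTime recording start time in seconds.
#' @export
setClass("Hypnogram",
  representation(labels = "factor", epochLengthS = "numeric",
                 startTime = "numeric")
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (!identical(levels(object@labels), STAGES5))
    msg <- c(msg, "labels must be a factor with levels Wake,N1,N2,N3,REM")
  if (anyNA(object@labels)) msg <- c(msg, "labels must not contain NA")
  if (!identical(object@epochLengthS, 30))
    msg <- c(msg, "epochLengthS is fixed at 30")
  if (length(msg)) msg else TRUE
})

#' SensorRecording: multichannel raw streams with per-channel rates
#'
#' @slot channels named list of numeric sample vectors
#'   (ecg, acc_x, acc_y, acc_z, spo2, temp_chest, temp_limb, hr_device).
#' @slot fs named numeric sampling rate (Hz) per channel.
#' @slot startTime start time in seconds.
#' @slot groundTruthRpeaks true R-peak times in seconds (synthetic data
#'   only; length 0 when unknown).
#' @slot groundTruthOffsetS known time offset of a duplicated ECG channel
#'   (synthetic only; NA when unknown).
#' @export
setClass("SensorRecording",
  representation(channels = "list", fs = "numeric", startTime = "numeric",
                 groundTruthRpeaks = "numeric",
                 groundTruthOffsetS = "numeric")
)

setValidity("SensorRecording", function(object) {
  msg <- character()
  if (!all(CHANNELS %in% names(object@channels)))
    msg <- c(msg, "channels must include all of: ",
             paste(CHANNELS, collapse = ", "))
  if (!all(CHANNELS %in% names(object@fs)) || any(object@fs <= 0))
    msg <- c(msg, "fs must be positive and named for every channel")
  if (length(msg)) return(paste(msg, collapse = "; "))
  lens <- vapply(object@channels[CHANNELS], length, integer(1))
  if (any(lens == 0)) msg <- c(msg, "every channel must be non-empty")
  durs <- lens / object@fs[CHANNELS]
  if (length(msg) == 0 && diff(range(durs)) > 30)
    msg <- c(msg, "channel durations must agree within one epoch (30 s)")
  sp <- object@channels$spo2
  if (length(sp) && (min(sp) < 0 || max(sp) > 100))
    msg <- c(msg, "SpO2 samples must lie in [0, 100]")
  tc <- c(object@channels$temp_chest, object@channels$temp_limb)
  if (length(tc) && (min(tc) < 20 || max(tc) > 45))
    msg <- c(msg, "temperatures must lie in [20, 45] deg C")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' RRSeries: R-peak times and successive R-R intervals
#'
#' @slot rpeakTimes strictly increasing R-peak times in seconds.
#' @slot rrIntervals successive differences in milliseconds
#'   (length = number of peaks - 1).
#' @export
setClass("RRSeries",
  representation(rpeakTimes = "numeric", rrIntervals = "numeric")
)

setValidity("RRSeries", function(object) {
  msg <- character()
  n <- length(object@rpeakTimes)
  if (n > 1 && any(diff(object@rpeakTimes) <= 0))
    msg <- c(msg, "rpeakTimes must be strictly increasing")
  if (length(object@rrIntervals) != max(0L, n - 1L))
    msg <- c(msg, "length(rrIntervals) must equal length(rpeakTimes) - 1")
  if (length(object@rrIntervals) && any(object@rrIntervals <= 0))
    msg <- c(msg, "rrIntervals must be positive")
  if (length(msg)) msg else TRUE
})

#' EpochFeatureTable: per-epoch feature matrix with stage labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`"features"`, 73 rows = features, columns = valid 30-s epochs),
#' `rowData` columns `feature` and `modality` (ACC/ECG/TEMP/SPO2) and
#' `colData` columns `subject_id`, `epoch_index`, `label5`, `label2`,
#' `label3`, `label4` and `valid`. Epochs rejected by the physiological
#' validity screen are recorded in `metadata(x)$excluded`.
#'
#' @export
setClass("EpochFeatureTable", contains = "SummarizedExperiment")

setValidity("EpochFeatureTable", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "epoch_index", "label5", "label2", "label3",
            "label4", "valid")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("feature", "modality") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'feature' and 'modality'")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: classifier, imbalance strategy, grid and seed
#'
#' The imbalance strategy is derived from the algorithm: bagging and
#' random forest use class weights plus random undersampling; gradient
#' boosting and XGBoost use SMOTE.
#'
#' @slot algorithm one of `"balanced_bagging"`, `"balanced_random_forest"`,
#'   `"gradient_boosting"`, `"xgboost"`.
#' @slot strategy `"weights_undersample"` or `"smote"` (derived).
#' @slot grid named list of hyperparameter value vectors.
#' @slot seed integer seed governing all modeling randomness.
#' @export
setClass("ModelSpec",
  representation(algorithm = "character", strategy = "character",
                 grid = "list", seed = "integer")
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  algs <- c("balanced_bagging", "balanced_random_forest",
            "gradient_boosting", "xgboost")
  if (!object@algorithm %in% algs)
    msg <- c(msg, paste("algorithm must be one of:",
                        paste(algs, collapse = ", ")))
  want <- if (object@algorithm %in% algs[1:2]) "weights_undersample"
          else "smote"
  if (length(object@algorithm) == 1 && object@algorithm %in% algs &&
      !identical(object@strategy, want))
    msg <- c(msg, sprintf("strategy for %s must be '%s'",
                          object@algorithm, want))
  if (length(object@grid) == 0 || any(lengths(object@grid) == 0))
    msg <- c(msg, "grid must be a non-empty named list of value vectors")
  if (length(msg)) msg else TRUE
})

#' CVResult: per-fold predictions from nested cross-validation
#'
#' @slot folds list; each element has `fold_id`, `truth`, `pred`
#'   (factors over the resolution's classes), `selected_features`,
#'   `hyperparameters`.
#' @slot framework `"population"` (leave-one-subject-out) or `"personal"`
#'   (stratified 10-fold within one subject).
#' @slot resolution number of collapsed stages (2, 3 or 4).
#' @slot classLevels class labels in canonical order.
#' @export
setClass("CVResult",
  representation(folds = "list", framework = "character",
                 resolution = "integer", classLevels = "character")
)

setValidity("CVResult", function(object) {
  msg <- character()
  if (!object@framework %in% c("population", "personal"))
    msg <- c(msg, "framework must be 'population' or 'personal'")
  if (!object@resolution %in% c(2L, 3L, 4L))
    msg <- c(msg, "resolution must be 2, 3 or 4")
  ok <- vapply(object@folds, function(f)
    length(f$truth) == length(f$pred), logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "each fold must have aligned truth and pred")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: pooled kappa, per-class metrics and confusion matrix
#'
#' @slot pooledKappa pooled Cohen's kappa over all test folds.
#' @slot perClass data.frame of one-vs-rest specificity, precision,
#'   sensitivity and F1 per class.
#' @slot balancedAccuracy arithmetic mean of per-class sensitivity.
#' @slot confusion pooled confusion matrix (rows = truth).
#' @slot confusionPct row-percentage confusion matrix.
#' @slot foldStats data.frame of per-fold metric mean and SEM.
#' @slot nEpochs total pooled test epochs.
#' @export
setClass("MetricsReport",
  representation(pooledKappa = "numeric", perClass = "data.frame",
                 balancedAccuracy = "numeric", confusion = "matrix",
                 confusionPct = "matrix", foldStats = "data.frame",
                 nEpochs = "integer")
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (!is.na(object@pooledKappa) &&
      (object@pooledKappa < -1 || object@pooledKappa > 1))
    msg <- c(msg, "pooledKappa must lie in [-1, 1]")
  if (sum(object@confusion) != object@nEpochs)
    msg <- c(msg, "confusion counts must sum to nEpochs")
  if (length(msg)) msg else TRUE
})

#' SleepArchitecture: total sleep time, stage percentages, awakenings
#'
#' @slot tstMin total sleep time in minutes (0.5 min per non-Wake epoch).
#' @slot stagePct percentage of total recording time per stage.
#' @slot nAwakenings maximal Wake runs strictly inside the sleep period.
#' @slot nEpochs number of epochs summarized.
#' @export
setClass("SleepArchitecture",
  representation(tstMin = "numeric", stagePct = "numeric",
                 nAwakenings = "integer", nEpochs = "integer")
)

setValidity("SleepArchitecture", function(object) {
  msg <- character()
  if (abs(sum(object@stagePct) - 100) > 0.1)
    msg <- c(msg, "stage percentages must sum to 100 (tol 0.1)")
  if (object@tstMin > object@nEpochs * 0.5 + 1e-9)
    msg <- c(msg, "total sleep time cannot exceed recording length")
  if (length(msg)) msg else TRUE
})
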