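## On-disk interchange and the end-to-end pipeline. The canonical format is
## human-auditable plain text: one CSV per channel (t_seconds, value), a
## hypnogram CSV (epoch_index, onset_s, stage) and a JSON manifest tying
## them together with sampling rates, units and provenance.

.CHANNEL_UNITS <- c(ecg = "mV", acc_x = "g", acc_y = "g", acc_z = "g",
                    spo2 = "%", temp_chest = "degC", temp_limb = "degC",
                    hr_device = "bpm")

#' Write a recording (and hypnogram) to per-channel CSV plus manifest
#'
#' @param recording a [SensorRecording-class].
#' @param dir output directory (created if needed).
#' @param hypnogram optional [Hypnogram-class] written alongside.
#' @param subjectId subject identifier recorded in the manifest.
#' @param seed seed recorded in the manifest (provenance only).
#' @return invisibly, the manifest path.
#' @export
writeRecording <- function(recording, dir, hypnogram = NULL,
                           subjectId = "s1", seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chanMap <- list()
  for (ch in CHANNELS) {
    fs <- recording@fs[[ch]]
    x <- recording@channels[[ch]]
    f <- paste0(ch, ".csv")
    df <- data.frame(t_seconds = (seq_along(x) - 1) / fs, value = x)
    write.csv(df, file.path(dir, f), row.names = FALSE)
    chanMap[[ch]] <- list(file = f, fs = fs,
                          units = unname(.CHANNEL_UNITS[ch]))
  }
  hypFile <- NULL
  if (!is.null(hypnogram)) {
    hypFile <- "hypnogram.csv"
    lab <- as.character(hypnogram@labels)
    write.csv(data.frame(epoch_index = seq_along(lab) - 1L,
                         onset_s = (seq_along(lab) - 1L) * 30,
                         stage = lab),
              file.path(dir, hypFile), row.names = FALSE)
  }
  man <- list(subject_id = subjectId, seed = seed,
              start_time = recording@startTime,
              channels = chanMap, hypnogram = hypFile,
              provenance = list(
                tool = paste0("SomnoStage ",
                              as.character(utils::packageVersion("SomnoStage")))))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a recording written by [writeRecording()]
#'
#' @param manifestPath path to `manifest.json`.
#' @return list with `recording` ([SensorRecording-class]), `hypnogram`
#'   ([Hypnogram-class] or NULL) and `subjectId`.
#' @export
readRecording <- function(manifestPath) {
  man <- jsonlite::read_json(manifestPath)
  dir <- dirname(manifestPath)
  chans <- list(); fs <- numeric(0)
  for (ch in CHANNELS) {
    entry <- man$channels[[ch]]
    if (is.null(entry)) stop("manifest is missing channel '", ch, "'")
    f <- file.path(dir, entry$file)
    if (!file.exists(f))
      stop("missing file for channel '", ch, "': ", entry$file)
    df <- read.csv(f)
    if (!all(c("t_seconds", "value") %in% names(df)))
      stop("malformed channel CSV for '", ch, "'")
    chans[[ch]] <- df$value
    fs[ch] <- as.numeric(entry$fs)
  }
  hyp <- NULL
  if (!is.null(man$hypnogram)) {
    hd <- read.csv(file.path(dir, man$hypnogram))
    hyp <- new("Hypnogram",
               labels = factor(hd$stage, levels = STAGES5),
               epochLengthS = 30, startTime = 0)
  }
  rec <- new("SensorRecording", channels = chans, fs = fs,
             startTime = as.numeric(man$start_time %||% 0),
             groundTruthRpeaks = numeric(0),
             groundTruthOffsetS = NA_real_)
  list(recording = rec, hypnogram = hyp,
       subjectId = man$subject_id %||% "s1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline: simulate, extract, model, evaluate, report
#'
#' Executes every stage under one global seed: cohort simulation, feature
#' extraction with exclusion bookkeeping, nested cross-validation in the
#' requested framework(s) and a written report bundle. Per-stage epoch
#' counts (used and excluded) are logged via `message()`.
#'
#' @param nSubjects cohort size.
#' @param durationH per-subject hours.
#' @param heterogeneity between-subject variation scale.
#' @param framework `"personal"` or `"population"`.
#' @param algorithm passed to [modelSpec()].
#' @param resolution stage resolution (2, 3 or 4).
#' @param seed global integer seed.
#' @param outDir optional report directory.
#' @param grid optional hyperparameter grid override.
#' @param innerFolds inner CV folds.
#' @return list with `table`, `results` (CVResult or list of), `metrics`
#'   ([MetricsReport-class] from the pooled predictions).
#' @export
runPipeline <- function(nSubjects = 3, durationH = 2, heterogeneity = 0,
                        framework = c("personal", "population"),
                        algorithm = "balanced_random_forest",
                        resolution = 2, seed = 1L, outDir = NULL,
                        grid = NULL, innerFolds = 10) {
  framework <- match.arg(framework)
  cohort <- generateCohort(nSubjects, heterogeneity, seed = seed,
                           durationH = durationH)
  table <- buildFeatureTable(cohort)
  excl <- S4Vectors::metadata(table)$excluded
  total <- ncol(table) + nrow(excl)
  message(sprintf("epochs: %d total = %d used + %d excluded",
                  total, ncol(table), nrow(excl)))
  spec <- modelSpec(algorithm, grid = grid, seed = as.integer(seed))
  if (framework == "population") {
    results <- nestedCV(table, spec, "population", resolution,
                        innerFolds = innerFolds)
    metrics <- perClassMetrics(results)
  } else {
    results <- personalModels(table, spec, resolution,
                              innerFolds = innerFolds)
    pooledFolds <- unlist(lapply(results, cvFolds), recursive = FALSE)
    pooled <- new("CVResult", folds = pooledFolds, framework = "personal",
                  resolution = as.integer(resolution),
                  classLevels = stageLevels(resolution))
    metrics <- perClassMetrics(pooled)
  }
  if (!is.null(outDir)) {
    rforReport <- if (is(results, "CVResult")) results else pooled
    writeReport(rforReport, outDir)
  }
  list(table = table, results = results, metrics = metrics)
}
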