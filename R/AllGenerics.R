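#' Accessors for SomnoStage classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setMethod("channels", "SensorRecording", function(x) x@channels)

#' @rdname accessors
#' @export
setGeneric("samplingRates", function(x) standardGeneric("samplingRates"))
#' @rdname accessors
#' @export
setMethod("samplingRates", "SensorRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("groundTruthRpeaks",
           function(x) standardGeneric("groundTruthRpeaks"))
#' @rdname accessors
#' @export
setMethod("groundTruthRpeaks", "SensorRecording",
          function(x) x@groundTruthRpeaks)

#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setMethod("epochLabels", "Hypnogram", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@labels))

#' @rdname accessors
#' @export
setGeneric("rpeakTimes", function(x) standardGeneric("rpeakTimes"))
#' @rdname accessors
#' @export
setMethod("rpeakTimes", "RRSeries", function(x) x@rpeakTimes)

#' @rdname accessors
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))
#' @rdname accessors
#' @export
setMethod("rrIntervals", "RRSeries", function(x) x@rrIntervals)

#' @rdname accessors
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))
#' @rdname accessors
#' @export
setMethod("cvFolds", "CVResult", function(x) x@folds)

#' @rdname accessors
#' @export
setGeneric("pooledTruth", function(x) standardGeneric("pooledTruth"))
#' @rdname accessors
#' @export
setMethod("pooledTruth", "CVResult", function(x)
  factor(unlist(lapply(x@folds, function(f) as.character(f$truth))),
         levels = x@classLevels))

#' @rdname accessors
#' @export
setGeneric("pooledPred", function(x) standardGeneric("pooledPred"))
#' @rdname accessors
#' @export
setMethod("pooledPred", "CVResult", function(x)
  factor(unlist(lapply(x@folds, function(f) as.character(f$pred))),
         levels = x@classLevels))

#' @rdname accessors
#' @export
setGeneric("pooledKappaValue", function(x) standardGeneric("pooledKappaValue"))
#' @rdname accessors
#' @export
setMethod("pooledKappaValue", "MetricsReport", function(x) x@pooledKappa)

#' @rdname accessors
#' @export
setGeneric("perClassTable", function(x) standardGeneric("perClassTable"))
#' @rdname accessors
#' @export
setMethod("perClassTable", "MetricsReport", function(x) x@perClass)

#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setMethod("confusionCounts", "MetricsReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setGeneric("totalSleepTime", function(x) standardGeneric("totalSleepTime"))
#' @rdname accessors
#' @export
setMethod("totalSleepTime", "SleepArchitecture", function(x) x@tstMin)

#' @rdname accessors
#' @export
setGeneric("stagePercentages", function(x) standardGeneric("stagePercentages"))
#' @rdname accessors
#' @export
setMethod("stagePercentages", "SleepArchitecture", function(x) x@stagePct)

#' @rdname accessors
#' @export
setGeneric("nAwakenings", function(x) standardGeneric("nAwakenings"))
#' @rdname accessors
#' @export
setMethod("nAwakenings", "SleepArchitecture", function(x) x@nAwakenings)

setMethod("show", "SensorRecording", function(object) {
  lens <- vapply(object@channels[CHANNELS], length, integer(1))
  cat("SensorRecording with", length(CHANNELS), "channels,",
      sprintf("%.2f h\n", lens[["ecg"]] / object@fs[["ecg"]] / 3600))
  for (ch in CHANNELS)
    cat(sprintf("  %-10s %6g Hz  %8d samples\n", ch,
                object@fs[[ch]], lens[[ch]]))
  if (length(object@groundTruthRpeaks))
    cat("  ground-truth R peaks:", length(object@groundTruthRpeaks), "\n")
})

setMethod("show", "Hypnogram", function(object) {
  cat("Hypnogram:", length(object@labels), "epochs of",
      object@epochLengthS, "s\n")
  print(table(object@labels))
})

setMethod("show", "RRSeries", function(object) {
  cat("RRSeries:", length(object@rpeakTimes), "peaks")
  if (length(object@rrIntervals))
    cat(sprintf(", mean RR %.0f ms", mean(object@rrIntervals)))
  cat("\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@algorithm, "| strategy:", object@strategy,
      "| seed:", object@seed, "\n  grid:",
      paste(sprintf("%s={%s}", names(object@grid),
                    vapply(object@grid, function(v)
                      paste(v, collapse = ","), character(1))),
            collapse = " "), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult:", object@framework, "framework,",
      object@resolution, "stages,", length(object@folds), "folds,",
      length(pooledTruth(object)), "pooled test epochs\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d epochs\n  pooled Cohen's kappa: %.3f (%s)\n  balanced accuracy:    %.3f\n",
              object@nEpochs, object@pooledKappa,
              kappaBand(object@pooledKappa), object@balancedAccuracy))
  print(round(object@perClass, 3))
})

setMethod("show", "SleepArchitecture", function(object) {
  cat(sprintf("SleepArchitecture: TST %.1f min, %d awakenings\n",
              object@tstMin, object@nAwakenings))
  print(round(object@stagePct, 1))
})
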