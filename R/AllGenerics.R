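#' Accessors for pulseTherm signal classes
#'
#' Small accessor layer over the S4 containers: slot access in user code is
#' discouraged.
#'
#' @param x an object of one of the pulseTherm classes.
#' @return The corresponding component (numeric vector, scalar or matrix).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("ppIntervals", function(x) standardGeneric("ppIntervals"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setGeneric("validIntervals", function(x) standardGeneric("validIntervals"))
#' @rdname accessors
#' @export
setGeneric("filteredTemps", function(x) standardGeneric("filteredTemps"))
#' @rdname accessors
#' @export
setGeneric("seriesStatus", function(x) standardGeneric("seriesStatus"))
#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setGeneric("meanF1", function(x) standardGeneric("meanF1"))

setMethod("signalValues", "EntropySignal", function(x) x@values)
setMethod("signalValues", "BvpSignal", function(x) x@values)
setMethod("signalValues", "ThermalSeries", function(x) x@temps)
setMethod("signalValues", "ThermalVariability", function(x) x@values)

setMethod("timestamps", "FrameStack", function(x) x@timestamps)
setMethod("timestamps", "EntropySignal", function(x) x@timestamps)
setMethod("timestamps", "ThermalSeries", function(x) x@timestamps)
setMethod("timestamps", "BvpSignal",
  function(x) x@t0 + (seq_along(x@values) - 1L) / x@rate)
setMethod("timestamps", "ThermalVariability",
  function(x) x@t0 + (seq_along(x@values) - 1L) / x@rate)

setMethod("sampleRate", "BvpSignal", function(x) x@rate)
setMethod("sampleRate", "ThermalVariability", function(x) x@rate)
setMethod("startTime", "BvpSignal", function(x) x@t0)
setMethod("startTime", "ThermalVariability", function(x) x@t0)

setMethod("ppIntervals", "PPIntervalSeries", function(x) x@intervals)
setMethod("peakTimes", "PPIntervalSeries", function(x) x@peakTimes)
setMethod("validIntervals", "PPIntervalSeries",
  function(x) x@intervals[x@valid])
setMethod("seriesStatus", "PPIntervalSeries", function(x) x@status)
setMethod("seriesStatus", "ThermalVariability", function(x) x@status)

setMethod("filteredTemps", "ThermalVariability", function(x) x@filteredC)

setMethod("foldAccuracies", "CvReport", function(x) x@foldAccuracy)
setMethod("confusionMatrix", "CvReport", function(x) x@confusion)
setMethod("meanAccuracy", "CvReport", function(x) mean(x@foldAccuracy))
setMethod("meanF1", "CvReport", function(x) x@meanF1)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameStack: %d frames of %dx%d px, %.2f-%.2f s (~%.1f fps)\n",
              length(object@frames), d[1L], d[2L],
              min(object@timestamps), max(object@timestamps),
              (length(object@frames) - 1) / diff(range(object@timestamps))))
})

setMethod("show", "EntropySignal", function(object) {
  cat(sprintf("EntropySignal: %d samples, range [%.3f, %.3f]\n",
              length(object@values), min(object@values), max(object@values)))
})

setMethod("show", "BvpSignal", function(object) {
  cat(sprintf("BvpSignal: %d samples at %g Hz starting t=%.3f s\n",
              length(object@values), object@rate, object@t0))
})

setMethod("show", "PPIntervalSeries", function(object) {
  cat(sprintf("PPIntervalSeries: %d peaks, %d intervals (%d valid), status '%s'\n",
              length(object@peakTimes), length(object@intervals),
              sum(object@valid), object@status))
  if (length(object@intervals))
    cat(sprintf("  mean PP %.1f ms (%.1f bpm)\n", mean(object@intervals),
                60000 / mean(object@intervals)))
})

setMethod("show", "ThermalSeries", function(object) {
  cat(sprintf("ThermalSeries: %d samples over %.1f s, %.2f-%.2f degC\n",
              length(object@temps), diff(range(object@timestamps)),
              min(object@temps), max(object@temps)))
})

setMethod("show", "ThermalVariability", function(object) {
  cat(sprintf("ThermalVariability: %d samples at %g Hz, status '%s', TD %.3f degC\n",
              length(object@values), object@rate, object@status,
              object@filteredC[length(object@filteredC)] - object@filteredC[1L]))
})

setMethod("show", "MeasurementWindow", function(object) {
  cat(sprintf("MeasurementWindow %s/%s: vas=%.2f label=%s [%s%s]\n",
              object@participantId, object@sessionId, object@vas, object@label,
              if (!is.null(object@pp)) "ppg " else "",
              if (!is.null(object@tv)) "thermal" else ""))
})

setMethod("show", "NNModel", function(object) {
  cat(sprintf("NNModel: %d inputs -> %d sigmoid hidden -> 1 sigmoid output (seed %d)\n",
              nrow(object@W1), object@hiddenSize, object@seed))
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport (%s, %s features, %s): %d folds\n", object@model,
              object@level, object@modality, length(object@foldAccuracy)))
  cat(sprintf("  mean accuracy %.2f%% (SD %.2f), mean F1 %.2f%%\n",
              100 * mean(object@foldAccuracy), 100 * sd(object@foldAccuracy),
              100 * object@meanF1))
  cat("  accumulated confusion (rows = truth):\n")
  print(object@confusion)
})
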