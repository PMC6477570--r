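#' @import methods
#' @importFrom stats approx rnorm runif sd spline var
#' @importFrom utils head read.csv tail write.csv
#' @useDynLib pulseTherm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' FrameStack: a time-stamped stack of single-channel 8-bit frames
#'
#' Container for the raw material of camera-based photoplethysmography: an
#' ordered sequence of single-channel (R-channel) 8-bit brightness frames with
#' per-frame timestamps in seconds. Frames are stored as integer matrices with
#' values in 0..255.
#'
#' @slot frames list of integer matrices, all with the same dimensions,
#'   pixel values in 0..255.
#' @slot timestamps numeric vector of acquisition times in seconds, strictly
#'   increasing, one per frame.
#'
#' @seealso [FrameStack()] for the constructor, [estimateRawBvp()],
#'   [extractPPG()].
#' @exportClass FrameStack
setClass("FrameStack",
  slots = c(frames = "list", timestamps = "numeric"))

setValidity("FrameStack", function(object) {
  msg <- character()
  n <- length(object@frames)
  if (n < 2L) msg <- c(msg, "a FrameStack needs at least 2 frames")
  if (length(object@timestamps) != n)
    msg <- c(msg, "timestamps must have one entry per frame")
  if (n >= 2L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (n >= 1L) {
    d0 <- dim(object@frames[[1L]])
    ok <- vapply(object@frames, function(f) {
      is.matrix(f) && identical(dim(f), d0) &&
        all(f >= 0) && all(f <= 255)
    }, logical(1L))
    if (!all(ok))
      msg <- c(msg, "all frames must be matrices of one shape with values in 0..255")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FrameStack-class Constructor.
#' @param frames list of 2-D numeric/integer matrices (values 0..255).
#' @param timestamps numeric vector of seconds, strictly increasing.
#' @return A `FrameStack` object.
#' @export
FrameStack <- function(frames, timestamps) {
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "integer"
    f
  })
  new("FrameStack", frames = frames, timestamps = as.numeric(timestamps))
}

#' EntropySignal: one value per frame on the native (irregular) time base
#'
#' Per-frame scalar series produced by [estimateRawBvp()]: either the negated
#' spatial Shannon entropy of each frame (the raw blood-volume-pulse estimate)
#' or the spatial mean brightness (the traditional baseline).
#'
#' @slot values numeric, one value per frame.
#' @slot timestamps numeric seconds, copied from the source [FrameStack-class].
#' @exportClass EntropySignal
setClass("EntropySignal",
  slots = c(values = "numeric", timestamps = "numeric"))

setValidity("EntropySignal", function(object) {
  if (length(object@values) != length(object@timestamps))
    return("values and timestamps must have equal length")
  if (length(object@timestamps) >= 2L && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  TRUE
})

#' BvpSignal: a uniformly sampled blood-volume-pulse signal
#'
#' Dimensionless BVP amplitude on a uniform grid, as produced by
#' [resampleUniform()] and [equalizeAmplitude()].
#'
#' @slot values numeric amplitude samples (finite).
#' @slot rate sampling rate in samples/s.
#' @slot t0 time of the first sample in seconds.
#' @exportClass BvpSignal
setClass("BvpSignal",
  slots = c(values = "numeric", rate = "numeric", t0 = "numeric"))

setValidity("BvpSignal", function(object) {
  if (length(object@rate) != 1L || object@rate <= 0)
    return("rate must be a single positive number")
  if (!all(is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' PPIntervalSeries: pulse-to-pulse intervals from detected BVP peaks
#'
#' The PPG low-level feature: ordered peak-to-peak intervals in milliseconds
#' together with the detected peak times. When validity filtering is enabled
#' intervals outside the physiologic 500--1250 ms range (120 down to 48 bpm)
#' are flagged invalid and excluded from downstream feature computation.
#'
#' @slot intervals numeric, PP intervals in ms (one fewer than peaks).
#' @slot peakTimes numeric, detected peak times in seconds.
#' @slot valid logical flag per interval (inside the physiologic band).
#' @slot status character, `"ok"` or a warning status such as
#'   `"too_few_peaks"`.
#' @exportClass PPIntervalSeries
setClass("PPIntervalSeries",
  slots = c(intervals = "numeric", peakTimes = "numeric",
            valid = "logical", status = "character"))

setValidity("PPIntervalSeries", function(object) {
  msg <- character()
  np <- length(object@peakTimes)
  if (length(object@intervals) != max(0L, np - 1L))
    msg <- c(msg, "intervals must number one fewer than peaks")
  if (length(object@valid) != length(object@intervals))
    msg <- c(msg, "valid must flag each interval")
  if (any(object@intervals <= 0))
    msg <- c(msg, "intervals must be positive")
  if (length(msg)) msg else TRUE
})

#' ThermalSeries: a time-stamped nose-tip ROI temperature sequence
#'
#' Spatial-average temperature of the tracked nose-tip region over time.
#' Irregular timestamp spacing is allowed (thermal cameras have unsteady
#' frame rates); values are degrees Celsius.
#'
#' @slot temps numeric, temperatures in deg C.
#' @slot timestamps numeric seconds, strictly increasing.
#' @exportClass ThermalSeries
setClass("ThermalSeries",
  slots = c(temps = "numeric", timestamps = "numeric"))

setValidity("ThermalSeries", function(object) {
  if (length(object@temps) != length(object@timestamps))
    return("temps and timestamps must have equal length")
  if (length(object@timestamps) >= 2L && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  if (!all(is.finite(object@temps)))
    return("temps must be finite")
  TRUE
})

#' @describeIn ThermalSeries-class Constructor; warns (only) when temperatures
#'   leave the plausible skin range of 10--45 deg C.
#' @param temps numeric temperatures in deg C.
#' @param timestamps numeric seconds, strictly increasing.
#' @return A `ThermalSeries`.
#' @export
ThermalSeries <- function(temps, timestamps) {
  obj <- new("ThermalSeries", temps = as.numeric(temps),
             timestamps = as.numeric(timestamps))
  if (any(temps < 10 | temps > 45))
    warning("temperatures outside the plausible skin range (10-45 degC)")
  obj
}

#' ThermalVariability: the 1 Hz respiration-filtered thermal variability sequence
#'
#' The thermal low-level feature: the respiration-filtered nose-tip
#' temperature resampled at 1 Hz and min-max scaled to \[0,1\] within the
#' measurement window. The unscaled filtered temperatures at the same grid are
#' retained so the temperature-difference (TD) feature can be computed in
#' degrees Celsius.
#'
#' @slot values numeric in \[0,1\] (all 0.5 for a constant window).
#' @slot rate samples/s (1 by construction).
#' @slot t0 time of the first sample in seconds.
#' @slot filteredC numeric, filtered temperatures in deg C at the same grid.
#' @slot status `"ok"` or `"constant"` when degenerate scaling applied.
#' @exportClass ThermalVariability
setClass("ThermalVariability",
  slots = c(values = "numeric", rate = "numeric", t0 = "numeric",
            filteredC = "numeric", status = "character"))

setValidity("ThermalVariability", function(object) {
  msg <- character()
  if (length(object@values) != length(object@filteredC))
    msg <- c(msg, "values and filteredC must have equal length")
  if (any(object@values < -1e-9 | object@values > 1 + 1e-9))
    msg <- c(msg, "scaled values must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' MeasurementWindow: one 20-second multimodal recording
#'
#' Ties together the two low-level features of a single instant measurement
#' (PP intervals and thermal variability), the participant/session identity
#' and the visual-analog-scale stress self-report. The binary label is set by
#' the labeling step before training.
#'
#' @slot participantId character scalar.
#' @slot sessionId character scalar (e.g. `"Rest1"`, `"Sh"`).
#' @slot pp a [PPIntervalSeries-class] or `NULL`.
#' @slot tv a [ThermalVariability-class] or `NULL`.
#' @slot vas numeric VAS score on \[0,10\] (cm).
#' @slot label character, `"NoStress"`, `"Stress"` or `NA`.
#' @exportClass MeasurementWindow
setClass("MeasurementWindow",
  slots = c(participantId = "character", sessionId = "character",
            pp = "ANY", tv = "ANY", vas = "numeric", label = "character"))

setValidity("MeasurementWindow", function(object) {
  if (is.null(object@pp) && is.null(object@tv))
    return("at least one modality (pp or tv) must be present")
  if (!is.null(object@pp) && !is(object@pp, "PPIntervalSeries"))
    return("pp must be a PPIntervalSeries or NULL")
  if (!is.null(object@tv) && !is(object@tv, "ThermalVariability"))
    return("tv must be a ThermalVariability or NULL")
  TRUE
})

#' @describeIn MeasurementWindow-class Constructor.
#' @param participantId,sessionId identifiers.
#' @param pp [PPIntervalSeries-class] or `NULL`.
#' @param tv [ThermalVariability-class] or `NULL`.
#' @param vas VAS score in \[0,10\].
#' @param label `"NoStress"`, `"Stress"`, or `NA`.
#' @return A `MeasurementWindow`.
#' @export
MeasurementWindow <- function(participantId, sessionId, pp = NULL, tv = NULL,
                              vas = NA_real_, label = NA_character_) {
  new("MeasurementWindow", participantId = as.character(participantId),
      sessionId = as.character(sessionId), pp = pp, tv = tv,
      vas = as.numeric(vas), label = as.character(label))
}

#' NNModel: a trained single-hidden-layer neural network
#'
#' Weights of a single-hidden-layer sigmoid network trained by per-sample
#' stochastic gradient descent (learning rate 0.5, 100 epochs by default),
#' together with the training-set mean/SD used to z-score features.
#'
#' @slot W1 input-to-hidden weight matrix (inputs x hidden).
#' @slot b1 hidden biases.
#' @slot W2 hidden-to-output weights.
#' @slot b2 output bias.
#' @slot mu,sigma training-set feature means and SDs (z-scoring).
#' @slot hiddenSize number of hidden nodes (80 for NN1, 260 for NN2).
#' @slot seed integer seed used for init and shuffling.
#' @exportClass NNModel
setClass("NNModel",
  slots = c(W1 = "matrix", b1 = "numeric", W2 = "numeric", b2 = "numeric",
            mu = "numeric", sigma = "numeric", hiddenSize = "integer",
            seed = "integer"))

setValidity("NNModel", function(object) {
  if (!all(is.finite(object@W1)) || !all(is.finite(object@W2)))
    return("weights must be finite")
  if (ncol(object@W1) != object@hiddenSize)
    return("hidden layer width must match hiddenSize")
  TRUE
})

#' CvReport: results of leave-one-subject-out cross-validation
#'
#' Per-fold accuracies, the confusion matrix accumulated (summed) over folds,
#' and the mean macro F1 across folds with a defined F1.
#'
#' @slot foldAccuracy named numeric, one accuracy per held-out participant.
#' @slot confusion 2x2 count matrix (rows = truth, cols = prediction).
#' @slot meanF1 mean of per-fold macro F1 scores (folds with undefined F1
#'   are skipped).
#' @slot model,modality,level character descriptors of the configuration.
#' @exportClass CvReport
setClass("CvReport",
  slots = c(foldAccuracy = "numeric", confusion = "matrix", meanF1 = "numeric",
            model = "character", modality = "character", level = "character"))

setValidity("CvReport", function(object) {
  if (!identical(dim(object@confusion), c(2L, 2L)))
    return("confusion must be 2x2")
  if (any(object@foldAccuracy < 0 | object@foldAccuracy > 1))
    return("fold accuracies must lie in [0,1]")
  TRUE
})
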