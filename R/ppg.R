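#' Spatial Shannon entropy of an 8-bit frame
#'
#' Computes the Shannon entropy (in bits) of the brightness histogram of a
#' single-channel frame. The histogram always uses `nbins` equal-width bins
#' over the full 8-bit range 0..255, the sensor convention, regardless of the
#' observed brightness range; empty bins contribute zero
#' (\eqn{0 \cdot \log 0 = 0}).
#'
#' The negated temporal sequence of this quantity over an R-channel frame
#' stack is the raw blood-volume-pulse estimate used throughout the package:
#' pulsatile blood volume perturbs the spread of the brightness distribution
#' even when the spatial mean barely moves.
#'
#' @param frame 2-D numeric/integer matrix with values in 0..255.
#' @param nbins number of histogram bins (>= 2, default 256).
#' @return Entropy in bits, in \[0, log2(nbins)\].
#' @examples
#' spatialEntropy(matrix(117, 8, 8))          # 0 bits
#' spatialEntropy(matrix(c(10, 10, 20, 30), 2, 2))  # 1.5 bits
#' @export
spatialEntropy <- function(frame, nbins = 256L) {
  if (length(frame) == 0L) stop("empty frame")
  if (!is.matrix(frame)) stop("frame must be a 2-D matrix")
  if (nbins < 2L) stop("nbins must be >= 2")
  v <- as.numeric(frame)
  if (any(v < 0 | v > 255)) stop("frame values must lie in 0..255")
  bin <- pmin(floor(v / (256 / nbins)), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins = nbins)
  p <- counts[counts > 0L] / length(v)
  -sum(p * log2(p))
}

#' Per-frame raw BVP series from a frame stack
#'
#' Reduces each frame of a [FrameStack-class] to one scalar. With
#' `method = "entropy"` the value is the negated spatial Shannon entropy,
#' the package's raw blood-volume-pulse estimate; `method = "mean_intensity"`
#' is the traditional baseline (spatial mean brightness of the R channel),
#' provided for comparison only.
#'
#' @param stack a [FrameStack-class].
#' @param method `"entropy"` (default) or `"mean_intensity"`.
#' @param nbins histogram bins for the entropy method.
#' @return An [EntropySignal-class] on the stack's native time base.
#' @export
estimateRawBvp <- function(stack, method = c("entropy", "mean_intensity"),
                           nbins = 256L) {
  stopifnot(is(stack, "FrameStack"))
  method <- match.arg(method)
  vals <- switch(method,
    entropy = -vapply(stack@frames, spatialEntropy, numeric(1L), nbins = nbins),
    mean_intensity = vapply(stack@frames, function(f) mean(as.numeric(f)),
                            numeric(1L)))
  new("EntropySignal", values = vals, timestamps = stack@timestamps)
}

#' Resample an irregular per-frame series to a uniform grid
#'
#' Cubic-spline interpolation of an [EntropySignal-class] onto a uniform grid
#' spanning \[first, last\] timestamp. The camera's native ~30 fps series is
#' upsampled (default 256 samples/s) so that peak positions, and hence PP
#' intervals, can be resolved well below the frame period.
#'
#' @param signal an [EntropySignal-class] with at least 4 samples.
#' @param rate target sampling rate in samples/s (default 256). Must exceed
#'   twice the native frame rate.
#' @return A [BvpSignal-class].
#' @export
resampleUniform <- function(signal, rate = 256) {
  stopifnot(is(signal, "EntropySignal"))
  ts <- signal@timestamps
  if (length(ts) < 4L) stop("need at least 4 samples for spline resampling")
  native <- (length(ts) - 1) / diff(range(ts))
  if (rate <= 2 * native)
    stop("target rate must exceed twice the native frame rate")
  grid <- seq(ts[1L], ts[length(ts)], by = 1 / rate)
  sf <- stats::splinefun(ts, signal@values, method = "fmm")
  new("BvpSignal", values = sf(grid), rate = rate, t0 = ts[1L])
}

#' Amplitude equalization by moving-average subtraction
#'
#' Subtracts the centered k-sample moving average from a uniform BVP signal,
#' where `k = round(windowS * rate)`. This removes slow baseline wander and
#' gives the successive pulse peaks similar amplitudes, which stabilizes
#' local-maxima peak detection. At the edges the window shrinks so the output
#' keeps the input length.
#'
#' The default window of 1 s spans at least one heartbeat for any plausible
#' resting heart rate, so the average tracks the baseline rather than the
#' pulse itself.
#'
#' @param signal a [BvpSignal-class].
#' @param windowS moving-average window in seconds (default 1.0).
#' @return A [BvpSignal-class] of the same length.
#' @export
equalizeAmplitude <- function(signal, windowS = 1.0) {
  stopifnot(is(signal, "BvpSignal"))
  if (windowS <= 0) stop("windowS must be positive")
  x <- signal@values
  n <- length(x)
  k <- round(windowS * signal@rate)
  if (k >= n) stop("moving-average window must be shorter than the signal")
  h1 <- floor((k - 1) / 2)
  h2 <- ceiling((k - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h1)
  hi <- pmin(n, i + h2)
  ma <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  new("BvpSignal", values = x - ma, rate = signal@rate, t0 = signal@t0)
}

#' PP-interval detection by windowed local maxima
#'
#' A sample is declared a peak iff it is the strict maximum of the centered
#' window of width `windowS` (default 0.5 s); ties are broken toward the
#' earlier sample. Successive peak-time differences (x 1000) are the PP
#' intervals in ms. The implied minimum inter-peak distance of `windowS`/2
#' and, when `validityFilter` is on, the \[500, 1250\] ms interval band
#' (120 down to 48 bpm) guard against spurious beats.
#'
#' Fewer than 2 peaks yields an empty series with status `"too_few_peaks"`
#' (a warning, not an error), since a flat or corrupted window is an expected
#' field condition.
#'
#' @param bvp a uniform [BvpSignal-class].
#' @param windowS sliding-window width in seconds (default 0.5).
#' @param validityFilter flag intervals outside 500--1250 ms as invalid
#'   (default `TRUE`; invalid intervals are excluded from features).
#' @param edgeGuardS discard peaks within this margin of the record ends, in
#'   seconds (default 0). Near the edges the preceding moving-average
#'   subtraction uses a truncated window, which biases peak positions there
#'   by tens of ms; [extractPPG()] guards half its moving-average window.
#' @return A [PPIntervalSeries-class].
#' @export
detectPPIntervals <- function(bvp, windowS = 0.5, validityFilter = TRUE,
                              edgeGuardS = 0) {
  stopifnot(is(bvp, "BvpSignal"))
  x <- bvp@values
  n <- length(x)
  h <- max(1L, floor(windowS * bvp@rate / 2))
  isPeak <- .Call(`_pulseTherm_local_maxima`, as.numeric(x), as.integer(h))
  pk <- which(isPeak)
  if (edgeGuardS > 0) {
    g <- edgeGuardS * bvp@rate
    pk <- pk[pk > g & pk <= n - g]
  }
  if (length(pk) < 2L) {
    warning("fewer than 2 peaks detected; returning empty PP series")
    return(new("PPIntervalSeries", intervals = numeric(0),
               peakTimes = bvp@t0 + (pk - 1L) / bvp@rate,
               valid = logical(0), status = "too_few_peaks"))
  }
  pt <- bvp@t0 + (pk - 1L) / bvp@rate
  iv <- diff(pt) * 1000
  valid <- if (validityFilter) iv >= 500 & iv <= 1250 else rep(TRUE, length(iv))
  new("PPIntervalSeries", intervals = iv, peakTimes = pt, valid = valid,
      status = "ok")
}

#' Full PPG extraction pipeline
#'
#' Composition of the extraction stages: per-frame negated spatial entropy,
#' cubic-spline upsampling to a uniform grid, moving-average amplitude
#' equalization, and windowed local-maxima PP detection. Both the equalized
#' BVP signal and the PP interval series are returned for inspection.
#'
#' By default the moving-average subtraction is applied after upsampling so
#' its window is well defined in seconds on a uniform grid;
#' `maBeforeResample = TRUE` applies it on the native frame grid instead
#' (window converted via the median frame period).
#'
#' @param stack a [FrameStack-class].
#' @param rate uniform sampling rate (default 256 samples/s).
#' @param maWindowS moving-average window in seconds (default 1.0).
#' @param peakWindowS peak-detection window in seconds (default 0.5).
#' @param method raw series method, `"entropy"` or `"mean_intensity"`.
#' @param nbins histogram bins (default 256).
#' @param validityFilter physiologic interval filter (default `TRUE`).
#' @param edgeGuardS peak-detection edge margin in seconds (default half the
#'   moving-average window, where the baseline estimate is biased).
#' @param maBeforeResample apply the moving-average stage before upsampling.
#' @return A list with elements `bvp` ([BvpSignal-class]) and
#'   `pp` ([PPIntervalSeries-class]).
#' @examples
#' rr <- generateRR(meanRR = 850, sdppTarget = 30, rmssdTarget = 25,
#'                  durationS = 20, seed = 1)
#' stack <- renderPpgFrames(rr, fps = 30, seed = 1)
#' res <- extractPPG(stack)
#' res$pp
#' @export
extractPPG <- function(stack, rate = 256, maWindowS = 1.0, peakWindowS = 0.5,
                       method = c("entropy", "mean_intensity"), nbins = 256L,
                       validityFilter = TRUE, edgeGuardS = maWindowS / 2,
                       maBeforeResample = FALSE) {
  method <- match.arg(method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("PPG stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  raw <- stage("entropy", estimateRawBvp(stack, method = method, nbins = nbins))
  if (maBeforeResample) {
    native <- stats::median(diff(raw@timestamps))
    k <- round(maWindowS / native)
    tmp <- new("BvpSignal", values = raw@values, rate = 1 / native,
               t0 = raw@timestamps[1L])
    eq <- stage("equalize", equalizeAmplitude(tmp, windowS = k * native))
    raw2 <- new("EntropySignal", values = eq@values, timestamps = raw@timestamps)
    bvp <- stage("resample", resampleUniform(raw2, rate = rate))
  } else {
    up <- stage("resample", resampleUniform(raw, rate = rate))
    bvp <- stage("equalize", equalizeAmplitude(up, windowS = maWindowS))
  }
  pp <- stage("detect",
              detectPPIntervals(bvp, windowS = peakWindowS,
                                validityFilter = validityFilter,
                                edgeGuardS = edgeGuardS))
  list(bvp = bvp, pp = pp)
}
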