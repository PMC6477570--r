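#' Spatial ROI mean temperature
#'
#' Reduces a sequence of nose-tip ROI pixel blocks to a per-frame spatial mean
#' temperature. ROI tracking itself is upstream of this package; this is the
#' fixed-ROI fallback for callers who have per-frame pixel blocks rather than
#' an already-averaged sequence.
#'
#' @param blocks list of non-empty numeric matrices/vectors of ROI pixel
#'   temperatures in deg C.
#' @param timestamps numeric seconds, strictly increasing.
#' @return A [ThermalSeries-class].
#' @export
roiMean <- function(blocks, timestamps) {
  if (any(vapply(blocks, length, integer(1L)) == 0L))
    stop("empty ROI pixel block")
  ThermalSeries(vapply(blocks, function(b) mean(as.numeric(b)), numeric(1L)),
                timestamps)
}

# Linear resampling of an irregular thermal series onto a uniform grid at the
# median native frame rate; Butterworth filtering needs uniform sampling.
uniformThermalGrid <- function(series) {
  ts <- series@timestamps
  dt <- stats::median(diff(ts))
  grid <- seq(ts[1L], ts[length(ts)], by = dt)
  vals <- stats::approx(ts, series@temps, xout = grid, rule = 2)$y
  list(temps = vals, grid = grid, rate = 1 / dt)
}

#' Remove respiratory oscillation from a nose-tip temperature sequence
#'
#' Breathing pushes warm exhaled air over the nose tip and contaminates the
#' slow vasoconstriction/dilation signal. Healthy adult breathing rates span
#' roughly 0.1--0.85 Hz, so the sequence is low-pass filtered with a cutoff
#' below that band (default 0.08 Hz) using a zero-phase (forward-backward)
#' 7th-order Butterworth filter, which leaves the slow thermal trend without
#' phase lag.
#'
#' The input is first linearly resampled onto a uniform grid at the median
#' native frame rate (thermal cameras have unsteady frame rates; IIR
#' filtering requires uniform sampling). The returned series lives on that
#' uniform grid.
#'
#' @param series a [ThermalSeries-class].
#' @param cutoffHz low-pass cutoff in Hz (default 0.08).
#' @param order filter order (default 7).
#' @return A uniformly sampled [ThermalSeries-class] of filtered temperatures.
#' @export
removeBreathing <- function(series, cutoffHz = 0.08, order = 7L) {
  stopifnot(is(series, "ThermalSeries"))
  u <- uniformThermalGrid(series)
  if (length(u$temps) < 8L * order)
    stop("series too short for stable zero-phase filtering (need >= ",
         8L * order, " uniform samples)")
  coef <- butterDesign(order, cutoffHz, u$rate, type = "low")
  filt <- zeroPhaseFilter(coef$b, coef$a, u$temps)
  new("ThermalSeries", temps = filt, timestamps = u$grid)
}

#' Thermal variability sequence: 1 Hz resampling and feature scaling
#'
#' Turns a filtered (uniform) temperature series into the thermal low-level
#' feature: linear interpolation at integer seconds from the first timestamp
#' (1 Hz addresses the camera's unsteady frame rate), then min-max scaling of
#' the window to \[0,1\] so that absolute nasal temperature levels, which
#' differ across people and sessions, do not dominate. The unscaled filtered
#' temperatures at the same 1 Hz grid are retained for the TD feature.
#'
#' A constant filtered window cannot be min-max scaled; by convention it maps
#' to all 0.5 with status `"constant"` and a warning.
#'
#' @param filtered a [ThermalSeries-class] (typically from
#'   [removeBreathing()]); span must be at least 5 s.
#' @param rate output rate in samples/s (default 1).
#' @return A [ThermalVariability-class] of length `floor(span)`.
#' @export
variabilitySequence <- function(filtered, rate = 1) {
  stopifnot(is(filtered, "ThermalSeries"))
  ts <- filtered@timestamps
  span <- ts[length(ts)] - ts[1L]
  if (span < 5) stop("window span must be at least 5 s")
  grid <- ts[1L] + seq(0, by = 1 / rate, length.out = floor(span * rate))
  raw <- stats::approx(ts, filtered@temps, xout = grid, rule = 2)$y
  rng <- range(raw)
  if (rng[2L] - rng[1L] < .Machine$double.eps * max(1, abs(rng[2L]))) {
    warning("constant filtered series; thermal variability set to 0.5")
    return(new("ThermalVariability", values = rep(0.5, length(raw)),
               rate = rate, t0 = grid[1L], filteredC = raw,
               status = "constant"))
  }
  scaled <- (raw - rng[1L]) / (rng[2L] - rng[1L])
  new("ThermalVariability", values = scaled, rate = rate, t0 = grid[1L],
      filteredC = raw, status = "ok")
}

#' Full thermal extraction pipeline
#'
#' [removeBreathing()] followed by [variabilitySequence()]: the nose-tip ROI
#' temperature sequence in, the 1 Hz min-max-scaled thermal variability
#' sequence out.
#'
#' @param series a [ThermalSeries-class].
#' @param cutoffHz low-pass cutoff in Hz (default 0.08).
#' @param order Butterworth order (default 7).
#' @return A [ThermalVariability-class].
#' @examples
#' th <- simulateThermal(durationS = 20, trendSlope = -0.05, seed = 2)
#' tv <- extractThermal(th)
#' tv
#' @export
extractThermal <- function(series, cutoffHz = 0.08, order = 7L) {
  variabilitySequence(removeBreathing(series, cutoffHz = cutoffHz,
                                      order = order))
}
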