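#' Relative power signal quality index (pSQI)
#'
#' Fraction of a signal's spectral power that lies inside an expected
#' physiological frequency band:
#' \deqn{pSQI = \int_{f_L}^{f_U} P(f)\,df \; / \; \int_{0^+}^{f_{Nyq}} P(f)\,df}
#' where \eqn{P} is the power spectral density. The mean is removed before
#' estimation so DC does not inflate the denominator; an optional band-pass
#' prefilter (zero-phase Butterworth) can suppress baseline wander and
#' high-frequency noise first. The result lies in \[0,1\] and is invariant to
#' amplitude scaling.
#'
#' The PSD estimator is Welch's method with Hann-windowed 10 s segments,
#' 50% overlap and per-segment linear detrending (variance reduction plus
#' suppression of slow-trend leakage, both suited to 20 s records); a plain
#' mean-detrended periodogram is available via `estimator = "periodogram"`.
#'
#' @param values uniformly sampled numeric signal (>= 32 samples).
#' @param rate sampling rate in samples/s.
#' @param fLow,fHigh band of interest in Hz, `0 < fLow < fHigh < rate/2`.
#' @param prefilter optional length-2 numeric band (Hz) for a zero-phase
#'   band-pass prefilter containing \[fLow, fHigh\], or `NULL`.
#' @param prefilterOrder Butterworth order of the prefilter (default 2,
#'   i.e. order 2 per passband edge).
#' @param estimator `"welch"` (default) or `"periodogram"`.
#' @param segmentS Welch segment length in seconds (default 10; `Inf` uses
#'   one full-record segment).
#' @param detrend per-segment detrending, `"linear"` (default) or `"mean"`.
#' @return The pSQI, a proportion in \[0,1\].
#' @examples
#' t <- seq(0, 20, by = 1 / 64)
#' psqi(sin(2 * pi * 1.2 * t), 64, 0.8, 2.0)  # ~1: all power in band
#' @export
psqi <- function(values, rate, fLow, fHigh, prefilter = NULL,
                 prefilterOrder = 2L, estimator = c("welch", "periodogram"),
                 segmentS = 10, detrend = c("linear", "mean")) {
  detrend <- match.arg(detrend)
  estimator <- match.arg(estimator)
  if (length(values) < 32L) stop("need at least 32 samples")
  if (!(fLow > 0 && fLow < fHigh && fHigh < rate / 2))
    stop("band must satisfy 0 < fLow < fHigh < Nyquist")
  x <- values - mean(values)
  if (!is.null(prefilter)) {
    if (length(prefilter) != 2L || prefilter[1L] > fLow || prefilter[2L] < fHigh)
      stop("prefilter band must contain [fLow, fHigh]")
    coef <- butterDesign(prefilterOrder, prefilter, rate, type = "pass")
    x <- zeroPhaseFilter(coef$b, coef$a, x)
    x <- x - mean(x)
  }
  if (sum(x^2) == 0) stop("zero-power signal: pSQI undefined")
  est <- if (estimator == "welch")
    welchPsd(x, rate, segmentS = segmentS, detrend = detrend)
  else periodogramPsd(x, rate)
  inband <- est$freq >= fLow & est$freq <= fHigh
  sum(est$psd[inband]) / sum(est$psd)
}

#' Cardiac pSQI of a BVP signal
#'
#' [psqi()] with the expected heart-rate band 0.8--2.0 Hz (48--120 bpm) after
#' a 0.7--4.0 Hz zero-phase band-pass prefilter that suppresses baseline
#' wander and high-frequency noise.
#'
#' @param bvp a [BvpSignal-class].
#' @param ... further arguments passed to [psqi()].
#' @return The cardiac pSQI in \[0,1\].
#' @export
cardiacPsqi <- function(bvp, ...) {
  stopifnot(is(bvp, "BvpSignal"))
  psqi(bvp@values, bvp@rate, fLow = 0.8, fHigh = 2.0,
       prefilter = c(0.7, 4.0), ...)
}

#' Respiratory pSQI of a thermal sequence
#'
#' [psqi()] with the expected breathing band 0.1--0.85 Hz and no prefilter.
#' Applied to a raw nose-tip sequence it quantifies respiratory
#' contamination; applied after [removeBreathing()] it should be small.
#' Because the band's lower edge (0.1 Hz) sits at the resolution limit of a
#' 10 s segment, this configuration uses one full-record Welch segment.
#'
#' @param x a [ThermalSeries-class] (must be uniformly sampled) or a numeric
#'   vector.
#' @param rate sampling rate in samples/s (required for a numeric vector;
#'   inferred from timestamps for a `ThermalSeries`).
#' @param ... further arguments passed to [psqi()].
#' @return The respiratory pSQI in \[0,1\].
#' @export
respiratoryPsqi <- function(x, rate = NULL, segmentS = Inf, ...) {
  if (is(x, "ThermalSeries")) {
    dt <- diff(x@timestamps)
    if (diff(range(dt)) > 1e-6 * mean(dt))
      stop("ThermalSeries must be uniformly sampled; resample first")
    rate <- 1 / mean(dt)
    x <- x@temps
  }
  if (is.null(rate)) stop("rate is required for a numeric vector")
  psqi(x, rate, fLow = 0.1, fHigh = 0.85, prefilter = NULL,
       segmentS = segmentS, ...)
}
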