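#' Pulse-rate-variability features from PP intervals
#'
#' Computes the six engineered PRV features from the valid PP intervals of a
#' window:
#' \describe{
#'   \item{lf_power, hf_power}{spectral power (ms^2) of the tachogram in the
#'     low-frequency (0.04--0.15 Hz) and high-frequency (0.15--0.40 Hz)
#'     bands. The tachogram (interval vs beat time) is linearly interpolated
#'     at 4 Hz, mean-removed, and its periodogram integrated over each band.}
#'   \item{lf_hf_ratio}{LF/HF power ratio (the classical sympathovagal
#'     index); `NA` when HF power is zero.}
#'   \item{sdpp}{sample SD of the intervals (ms).}
#'   \item{rmssd}{root-mean-square of successive interval differences (ms).}
#'   \item{ppp50}{proportion of successive differences whose absolute value
#'     exceeds 50 ms, relative to the number of intervals (the package's
#'     default; `ppp50Denominator = "differences"` gives the conventional
#'     pNN50-style denominator).}
#' }
#'
#' Time-domain features need at least 4 valid intervals, frequency-domain
#' features at least 8; features that cannot be computed are returned as
#' `NA` (missing), never silently as zero. On 20 s records the LF estimate
#' in particular is acknowledged low-resolution; no sliding window is used.
#'
#' @param pp a [PPIntervalSeries-class].
#' @param interpRate tachogram interpolation rate in Hz (default 4).
#' @param ppp50Denominator `"intervals"` (default) or `"differences"`.
#' @param normalized return LF and HF as fractions of total (LF+HF) power
#'   instead of absolute ms^2 (default `FALSE`).
#' @return Named numeric vector with elements `lf_power`, `hf_power`,
#'   `lf_hf_ratio`, `sdpp`, `rmssd`, `ppp50`.
#' @examples
#' pp <- new("PPIntervalSeries", intervals = c(800, 810, 790, 805),
#'           peakTimes = cumsum(c(0, 800, 810, 790, 805)) / 1000,
#'           valid = rep(TRUE, 4), status = "ok")
#' prvFeatures(pp)[["rmssd"]]  # ~15.546 ms
#' @export
prvFeatures <- function(pp, interpRate = 4, ppp50Denominator = c("intervals",
                        "differences"), normalized = FALSE) {
  stopifnot(is(pp, "PPIntervalSeries"))
  ppp50Denominator <- match.arg(ppp50Denominator)
  keep <- pp@valid
  iv <- pp@intervals[keep]
  out <- c(lf_power = NA_real_, hf_power = NA_real_, lf_hf_ratio = NA_real_,
           sdpp = NA_real_, rmssd = NA_real_, ppp50 = NA_real_)
  if (length(iv) >= 4L) {
    d <- diff(iv)
    out["sdpp"] <- sd(iv)
    out["rmssd"] <- sqrt(mean(d^2))
    denom <- if (ppp50Denominator == "intervals") length(iv) else length(d)
    out["ppp50"] <- sum(abs(d) > 50) / denom
  }
  if (length(iv) >= 8L) {
    # tachogram over the beat-time axis: each interval at its ending peak
    bt <- pp@peakTimes[-1L][keep]
    grid <- seq(bt[1L], bt[length(bt)], by = 1 / interpRate)
    if (length(grid) >= 16L) {
      tach <- stats::approx(bt, iv, xout = grid)$y
      est <- periodogramPsd(tach - mean(tach), interpRate)
      bandPower <- function(lo, hi) {
        sel <- est$freq >= lo & est$freq <= hi
        sum(est$psd[sel]) * (est$freq[2L] - est$freq[1L])
      }
      lf <- bandPower(0.04, 0.15)
      hf <- bandPower(0.15, 0.40)
      if (normalized) {
        tot <- lf + hf
        out["lf_power"] <- if (tot > 0) lf / tot else NA_real_
        out["hf_power"] <- if (tot > 0) hf / tot else NA_real_
      } else {
        out["lf_power"] <- lf
        out["hf_power"] <- hf
      }
      out["lf_hf_ratio"] <- if (hf > 0) lf / hf else NA_real_
    }
  }
  out
}

#' Thermal features from a thermal variability sequence
#'
#' The three engineered nose-tip features:
#' \describe{
#'   \item{td}{Temperature Difference, last minus first value of the
#'     retained filtered deg C series (signed: negative values mean the nose
#'     tip cooled, the classical sympathetic vasoconstriction signature).}
#'   \item{sdstv}{sample SD of successive differences of the scaled
#'     variability sequence.}
#'   \item{sdtv}{sample SD of the scaled variability sequence.}
#' }
#' TD is computed on temperatures (not the \[0,1\]-scaled values) because it
#' is a temperature difference in the literature it comes from; the two SD
#' features are computed on the scaled sequence. For a constant (status
#' `"constant"`) window the features are computed on the 0.5-convention
#' values, so all three are zero.
#'
#' @param tv a [ThermalVariability-class] of length >= 3.
#' @return Named numeric vector with elements `td`, `sdstv`, `sdtv`.
#' @export
thermalFeatures <- function(tv) {
  stopifnot(is(tv, "ThermalVariability"))
  n <- length(tv@values)
  if (n < 3L) stop("thermal variability sequence must have >= 3 samples")
  c(td = tv@filteredC[n] - tv@filteredC[1L],
    sdstv = sd(diff(tv@values)),
    sdtv = sd(tv@values))
}

#' High-level feature vector of a measurement window
#'
#' Concatenates the 6 PRV and 3 thermal features of a
#' [MeasurementWindow-class] according to the requested modality. Missing
#' modalities or uncomputable features are `NA`.
#'
#' @param window a [MeasurementWindow-class].
#' @param modality `"multimodal"`, `"ppg_only"` or `"thermal_only"`.
#' @param ... passed to [prvFeatures()].
#' @return Named numeric vector (9, 6 or 3 elements).
#' @export
highLevelFeatures <- function(window, modality = c("multimodal", "ppg_only",
                              "thermal_only"), ...) {
  modality <- match.arg(modality)
  prv <- if (modality != "thermal_only") {
    if (is.null(window@pp)) rep(NA_real_, 6L) else prvFeatures(window@pp, ...)
  }
  th <- if (modality != "ppg_only") {
    if (is.null(window@tv)) rep(NA_real_, 3L) else thermalFeatures(window@tv)
  }
  out <- c(prv, th)
  names(out) <- c(if (modality != "thermal_only")
                    c("lf_power", "hf_power", "lf_hf_ratio", "sdpp", "rmssd",
                      "ppp50"),
                  if (modality != "ppg_only") c("td", "sdstv", "sdtv"))
  out
}
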