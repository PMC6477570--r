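# Synthetic-data generators: planted RR series, pulse-modulated frame
# stacks, breathing-contaminated thermal series, and full scored cohorts.
# These emulate a lab stress protocol (17 participants, 6 sessions of
# rest/easy/hard stressor tasks, 20 s windows at ~30 fps camera and ~8 fps
# thermal frame rates) so the whole pipeline is testable without recordings.

#' Generate a ground-truth PP interval series
#'
#' Autoregressive (AR(1)) Gaussian interval generator calibrated so the
#' realized SDPP and RMSSD track the requested targets: for a stationary
#' AR(1) with marginal SD \eqn{\sigma} and lag-1 autocorrelation \eqn{\phi},
#' RMSSD \eqn{= \sigma\sqrt{2(1-\phi)}}, so \eqn{\phi = 1 - r^2/(2\sigma^2)}
#' (clamped to \[-0.999, 0.999\]). Intervals are clipped to the physiologic
#' 500--1250 ms band. Targets with `rmssdTarget > 2*sqrt(2)*sdppTarget` are
#' rejected; note that an AR(1) saturates near RMSSD = 2*SDPP, so targets
#' beyond that are accepted but cannot be realized exactly.
#'
#' @param meanRR mean interval in ms (500--1250).
#' @param sdppTarget target SD of intervals (ms).
#' @param rmssdTarget target RMSSD (ms).
#' @param durationS total duration to cover in seconds.
#' @param seed integer seed.
#' @return A [PPIntervalSeries-class] whose peaks start at t = 0.
#' @export
generateRR <- function(meanRR = 850, sdppTarget = 30, rmssdTarget = 25,
                       durationS = 20, seed = 1L) {
  if (meanRR < 500 || meanRR > 1250)
    stop("meanRR must lie in [500, 1250] ms")
  if (sdppTarget < 0 || rmssdTarget < 0) stop("targets must be >= 0")
  if (rmssdTarget > 2 * sqrt(2) * sdppTarget)
    stop("infeasible targets: rmssd > 2*sdpp*sqrt(2)")
  n <- ceiling(durationS * 1000 / max(1, meanRR - 3 * sdppTarget)) + 2L
  iv <- withSeed(seed, {
    if (sdppTarget == 0) rep(meanRR, n)
    else {
      phi <- max(-0.999, min(0.999, 1 - (rmssdTarget / sdppTarget)^2 / 2))
      x <- numeric(n)
      x[1L] <- rnorm(1L, 0, sdppTarget)
      innov <- rnorm(n - 1L, 0, sdppTarget * sqrt(1 - phi^2))
      for (i in 2:n) x[i] <- phi * x[i - 1L] + innov[i - 1L]
      meanRR + x
    }
  })
  iv <- pmin(1250, pmax(500, iv))
  cum <- cumsum(iv) / 1000
  keep <- seq_len(min(n, which(cum >= durationS)[1L], na.rm = TRUE))
  iv <- iv[keep]
  pt <- c(0, cumsum(iv) / 1000)
  new("PPIntervalSeries", intervals = iv, peakTimes = pt,
      valid = rep(TRUE, length(iv)), status = "ok")
}

# Piecewise-linear cardiac phase: advances by 1 between successive planted
# peaks, extrapolating with the first/last interval beyond the ends.
cardiacPhase <- function(peakTimes, t) {
  n <- length(peakTimes)
  ph <- stats::approx(peakTimes, seq_len(n) - 1L, xout = t, rule = 2)$y
  lo <- t < peakTimes[1L]
  hi <- t > peakTimes[n]
  if (any(lo))
    ph[lo] <- (t[lo] - peakTimes[1L]) / (peakTimes[2L] - peakTimes[1L])
  if (any(hi))
    ph[hi] <- (n - 1L) + (t[hi] - peakTimes[n]) /
      (peakTimes[n] - peakTimes[n - 1L])
  ph
}

#' Render a pulse-modulated PPG frame stack
#'
#' Produces a synthetic R-channel frame stack whose brightness-histogram
#' *spread* (hence spatial entropy) oscillates with a cardiac waveform driven
#' by a planted PP interval series, while the spatial mean is held
#' approximately constant. At each planted beat the spread is minimal, so the
#' negated-entropy BVP estimate peaks exactly at the planted beat times; the
#' mean-intensity baseline sees almost nothing. `mode = "mean"` instead
#' modulates the spatial mean at constant spread, the regime where the
#' traditional method succeeds too.
#'
#' Each stack uses one fixed zero-mean spatial pattern scaled per frame, a
#' cheap stand-in for speckle whose width breathes with blood volume.
#'
#' @param rr a [PPIntervalSeries-class] of planted intervals.
#' @param fps frame rate (>= 20; default 30).
#' @param frameShape frame dimensions in pixels (default 64 x 64). Smaller
#'   crops under-resolve the brightness histogram: entropy quantization
#'   noise at 32 x 32 jitters recovered peak positions by several ms.
#' @param modulationDepth relative modulation in (0, 1\] (default 0.4).
#' @param seed integer seed for the spatial pattern.
#' @param mode `"entropy"` (spread-modulated, default) or `"mean"`.
#' @param baseSpread baseline brightness SD in grey levels (default 28).
#' @return A [FrameStack-class].
#' @export
renderPpgFrames <- function(rr, fps = 30, frameShape = c(64L, 64L),
                            modulationDepth = 0.4, seed = 1L,
                            mode = c("entropy", "mean"), baseSpread = 28) {
  stopifnot(is(rr, "PPIntervalSeries"))
  mode <- match.arg(mode)
  if (fps < 20) stop("fps must be >= 20")
  if (modulationDepth <= 0 || modulationDepth > 1)
    stop("modulationDepth must lie in (0, 1]")
  pt <- rr@peakTimes
  t <- seq(pt[1L], pt[length(pt)], by = 1 / fps)
  w <- cos(2 * pi * cardiacPhase(pt, t))
  npx <- prod(frameShape)
  z <- withSeed(seed, rnorm(npx))
  z <- (z - mean(z)) / sd(z)
  frames <- if (mode == "entropy") {
    s <- baseSpread * (1 - modulationDepth * 0.5 * (1 + w))
    lapply(seq_along(t), function(i) {
      v <- round(128 + s[i] * z)
      matrix(pmin(255L, pmax(0L, as.integer(v))), frameShape[1L],
             frameShape[2L])
    })
  } else {
    m <- 128 + modulationDepth * 40 * w
    lapply(seq_along(t), function(i) {
      v <- round(m[i] + baseSpread * 0.5 * z)
      matrix(pmin(255L, pmax(0L, as.integer(v))), frameShape[1L],
             frameShape[2L])
    })
  }
  FrameStack(frames, t)
}

#' Simulate a nose-tip temperature sequence
#'
#' Additive model of the thermal channel:
#' `temp(t) = baseTemp + trendSlope*t + breathingAmp*sin(2*pi*breathingHz*t)
#' + noise`, sampled on a nominal grid with Gaussian timestamp jitter
#' (thermal cameras have unsteady frame rates). A negative trend emulates
#' stress-related nasal vasoconstriction cooling; the sinusoid emulates
#' respiratory contamination.
#'
#' @param baseTemp baseline temperature in deg C (default 34).
#' @param breathingHz breathing frequency, within 0.1--0.85 Hz (default 0.3).
#' @param breathingAmp breathing oscillation amplitude in deg C (default 0.1).
#' @param trendSlope linear trend in deg C/s (negative = cooling; default 0).
#' @param noiseSd sensor noise SD in deg C (default 0.02).
#' @param jitterSd timestamp jitter SD in seconds (default 0.01).
#' @param fps nominal frame rate (default 8).
#' @param durationS duration in seconds (>= 10; default 20).
#' @param seed integer seed.
#' @return A [ThermalSeries-class].
#' @export
simulateThermal <- function(baseTemp = 34, breathingHz = 0.3,
                            breathingAmp = 0.1, trendSlope = 0,
                            noiseSd = 0.02, jitterSd = 0.01, fps = 8,
                            durationS = 20, seed = 1L) {
  if (breathingHz < 0.1 || breathingHz > 0.85)
    stop("breathingHz must lie in the breathing band [0.1, 0.85] Hz")
  if (durationS < 10) stop("durationS must be >= 10 s")
  withSeed(seed, {
    tnom <- seq(0, durationS, by = 1 / fps)
    ts <- sort(tnom + rnorm(length(tnom), 0, jitterSd))
    ts <- ts - ts[1L]
    # enforce strict monotonicity after jitter
    ts <- cummax(ts + seq_along(ts) * 1e-9)
    temps <- baseTemp + trendSlope * ts +
      breathingAmp * sin(2 * pi * breathingHz * ts) +
      rnorm(length(ts), 0, noiseSd)
    ThermalSeries(temps, ts)
  })
}

#' Generate a synthetic multi-participant scored cohort
#'
#' Emulates a 17-participant, 6-session lab protocol (Rest1, Stroop easy,
#' Stroop hard, Rest2, Math easy, Math hard). Each session draws a latent
#' stress level (rest < easy < hard on average, with participant-level
#' noise) that is mapped to: a planted RR series with lower RMSSD under
#' stress, a thermal series with a more negative (vasoconstriction) trend
#' under stress, and a VAS self-report with participant-specific bias and
#' range compression - the interpersonal variability that per-participant
#' normalization must fix.
#'
#' Participants also differ physiologically: each draws a baseline mean RR
#' interval, baseline RMSSD and a thermal trend bias, emulating the large
#' between-person spread of resting heart-rate variability and nasal
#' temperature dynamics. Under leave-one-subject-out evaluation this
#' heterogeneity is what makes generalizing to an unseen person hard.
#'
#' The emitted truth label is `"Stress"` for task sessions and `"NoStress"`
#' for rests, the planted ground truth the classifiers should recover.
#'
#' @param nParticipants number of participants (>= 3; default 17).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   it.
#' @param rmssdEffect fractional RMSSD suppression at full stress, in
#'   \[0, 0.9\] (default 0.35, i.e. about a one-third drop under hard
#'   stressors; 0.5 plants a halving). The effect is multiplicative because
#'   heart-rate-variability indices scale with the person's own baseline.
#' @param slopeEffect thermal trend decrement (deg C/s) at full stress
#'   (default 0.03).
#' @param vasEffect multiplier on the stress-to-VAS mapping (default 1).
#' @param vasBiasSd SD of the participant-level VAS offset (default 1).
#' @param vasRangeSd SD of the participant-level VAS range compression
#'   (default 0.15, around a mean gain of 0.7).
#' @param rmssdBaseCv log-scale SD (coefficient of variation) of the
#'   log-normal participant baseline RMSSD around 45 ms (default 0.35,
#'   matching the large between-person spread of resting HRV).
#' @param meanRRSd SD of the participant baseline mean RR around 850 ms
#'   (default 60).
#' @param slopeBiasSd SD of the participant thermal trend bias in deg C/s
#'   (default 0.01; resting nasal temperature drifts on the order of the
#'   stress effect itself).
#' @param durationS window length in seconds (default 20).
#' @param fps camera frame rate (default 30).
#' @param frameShape camera frame dimensions (default 64 x 64; see
#'   [renderPpgFrames()]).
#' @param renderFrames render the PPG frame stacks (default `TRUE`); when
#'   `FALSE` the `stack` entries are `NULL` and only the planted RR series
#'   carry the PPG channel (a fast path for signal-level experiments).
#' @param sessions session identifiers (default the six protocol sessions).
#' @param sessionStress named base latent stress level per session id in
#'   \[0,1\] (default rests 0.10, easy tasks 0.55, hard tasks 0.90); setting
#'   easy = hard = 1 and rests = 0 plants a maximal binary contrast.
#' @return List with elements `inputs` (one entry per window:
#'   `participantId`, `sessionId`, `stack`, `thermal`, `rr` (planted),
#'   `stress` (latent level)), `scores` (a ScoreTable data.frame) and
#'   `truth` (data.frame with the planted binary labels).
#' @export
generateCohort <- function(nParticipants = 17L, seed = 1L, rmssdEffect = 0.35,
                           slopeEffect = 0.03, vasEffect = 1, vasBiasSd = 1,
                           vasRangeSd = 0.15, rmssdBaseCv = 0.35, meanRRSd = 60,
                           slopeBiasSd = 0.01, durationS = 20, fps = 30,
                           frameShape = c(64L, 64L), renderFrames = TRUE,
                           sessions = c("Rest1", "Se", "Sh", "Rest2", "Me",
                                        "Mh"),
                           sessionStress = c(Rest1 = 0.10, Se = 0.55,
                                             Sh = 0.90, Rest2 = 0.10,
                                             Me = 0.55, Mh = 0.90)) {
  if (nParticipants < 3L) stop("need at least 3 participants")
  if (rmssdEffect < 0 || slopeEffect < 0 || vasEffect < 0)
    stop("effect sizes must be >= 0")
  if (rmssdEffect > 0.9)
    stop("rmssdEffect is a fractional suppression and must be <= 0.9")
  base <- sessionStress
  stressSessions <- c("Se", "Sh", "Me", "Mh")
  withSeed(seed, {
    inputs <- list()
    rows <- list()
    for (p in seq_len(nParticipants)) {
      pid <- sprintf("P%02d", p)
      bias <- abs(rnorm(1L, 0, vasBiasSd))
      gain <- min(1, max(0.3, rnorm(1L, 0.7, vasRangeSd)))
      pshift <- rnorm(1L, 0, 0.05)
      rmssdBase <- min(120, max(15, exp(rnorm(1L, log(45), rmssdBaseCv))))
      meanRRp <- min(1100, max(600, rnorm(1L, 850, meanRRSd)))
      slopeBias <- rnorm(1L, 0, slopeBiasSd)
      for (s in sessions) {
        z <- min(1, max(0, (if (s %in% names(base)) base[[s]] else 0.5) +
                          pshift + rnorm(1L, 0, 0.06)))
        rmssd <- max(5, rmssdBase * (1 - rmssdEffect * z))
        wseed <- sample.int(.Machine$integer.max - 1L, 1L)
        rr <- generateRR(meanRR = meanRRp, sdppTarget = rmssd,
                         rmssdTarget = rmssd, durationS = durationS,
                         seed = wseed)
        stack <- if (renderFrames)
          renderPpgFrames(rr, fps = fps, frameShape = frameShape,
                          seed = wseed + 1L)
        thermal <- simulateThermal(
          baseTemp = 34 + rnorm(1L, 0, 0.5), breathingHz = runif(1L, 0.2, 0.5),
          breathingAmp = 0.1, trendSlope = slopeBias - slopeEffect * z,
          noiseSd = 0.02, durationS = durationS, seed = wseed + 2L)
        vas <- min(10, max(0, bias + gain * 10 * vasEffect * z +
                             rnorm(1L, 0, 0.4)))
        inputs[[length(inputs) + 1L]] <-
          list(participantId = pid, sessionId = s, stack = stack,
               thermal = thermal, rr = rr, stress = z)
        rows[[length(rows) + 1L]] <-
          data.frame(participant_id = pid, session_id = s, vas = vas,
                     truth = if (s %in% stressSessions) "Stress" else
                       "NoStress")
      }
    }
    tab <- do.call(rbind, rows)
    list(inputs = inputs,
         scores = tab[, c("participant_id", "session_id", "vas")],
         truth = tab[, c("participant_id", "session_id", "truth")])
  })
}

#' Run the extraction pipeline over a synthetic cohort
#'
#' Converts a [generateCohort()] result into labelled-ready
#' [MeasurementWindow-class] objects: PP intervals come from [extractPPG()]
#' on each frame stack (or from the planted RR series when
#' `usePlantedPP = TRUE` or frames were not rendered) and thermal variability
#' from [extractThermal()] on each thermal series.
#'
#' @param cohort result of [generateCohort()].
#' @param usePlantedPP bypass PPG extraction and use the planted RR series.
#' @param ... passed to [extractPPG()].
#' @return List of [MeasurementWindow-class] objects (unlabelled).
#' @export
extractCohortWindows <- function(cohort, usePlantedPP = FALSE, ...) {
  scoreKey <- paste(cohort$scores$participant_id, cohort$scores$session_id)
  lapply(cohort$inputs, function(inp) {
    pp <- if (usePlantedPP || is.null(inp$stack)) inp$rr
          else suppressWarnings(extractPPG(inp$stack, ...)$pp)
    tv <- extractThermal(inp$thermal)
    vas <- cohort$scores$vas[match(paste(inp$participantId, inp$sessionId),
                                   scoreKey)]
    MeasurementWindow(inp$participantId, inp$sessionId, pp = pp, tv = tv,
                      vas = vas)
  })
}
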