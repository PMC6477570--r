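test_that("roiMean averages ROI blocks into a ThermalSeries", {
  blocks <- list(matrix(c(33, 35), 1, 2), matrix(34, 2, 2))
  ts <- roiMean(blocks, c(0, 0.125))
  expect_s4_class(ts, "ThermalSeries")
  expect_equal(signalValues(ts), c(34, 34))
})

test_that("zero-phase filter has unit passband gain and no phase shift", {
  # the 7th-order 0.08 Hz filter settles over ~25 s, so judge the interior
  # of a long record
  rate <- 8
  t <- seq(0, 200, by = 1 / rate)
  x <- sin(2 * pi * 0.02 * t)          # well inside the 0.08 Hz passband
  coef <- butterDesign(7, 0.08, rate, type = "low")
  y <- zeroPhaseFilter(coef$b, coef$a, x)
  inner <- t > 40 & t < 160
  expect_lt(max(abs(y[inner] - x[inner])), 5e-3)
})

test_that("step response of the steady-state initialized filter is flat", {
  coef <- butterDesign(4, 0.1, 2, type = "low")
  zi <- pulseTherm:::lfilterZi(coef$b, coef$a)
  y <- pulseTherm:::dfilt(coef$b, coef$a, rep(1, 50), zi)
  dc <- sum(coef$b) / sum(coef$a)
  expect_lt(max(abs(y - dc)), 1e-12)
})

test_that("removeBreathing attenuation matches the analytic magnitude", {
  # pure-sinusoid oracle on a long record; the interior segment avoids the
  # filter's ~25 s settling transient at the record edges
  rate <- 8
  t <- seq(0, 240, by = 1 / rate)
  coef <- butterDesign(7, 0.08, rate, type = "low")
  for (f in c(0.1, 0.3, 0.85)) {
    ts <- ThermalSeries(34 + 0.2 * sin(2 * pi * f * t), t)
    filt <- removeBreathing(ts)
    # forward-backward pass: gain |H(f)|^2
    gain <- pulseTherm:::butterMagnitude(coef, f, rate)^2
    inner <- t >= 60 & t <= 180
    resid <- signalValues(filt)[inner] - 34
    # complex demodulation over a whole number of cycles
    ncyc <- floor(120 * f)
    sel <- t[inner] - 60 < ncyc / f
    amp <- 2 * abs(mean(resid[sel] * exp(-2i * pi * f * t[inner][sel])))
    expect_lt(abs(amp - 0.2 * gain), pmax(0.05 * 0.2 * gain, 2e-5))
  }
})

test_that("variabilitySequence scales to [0,1] on a 1 Hz grid", {
  t <- seq(0, 20, by = 1 / 8)
  ts <- ThermalSeries(34 - 0.02 * t, t)
  tv <- variabilitySequence(ts)
  expect_equal(sampleRate(tv), 1)
  expect_length(signalValues(tv), 20)
  expect_equal(range(signalValues(tv)), c(0, 1))
  expect_equal(length(filteredTemps(tv)), 20)
})

test_that("constant thermal windows use the 0.5 convention", {
  t <- seq(0, 15, by = 0.5)
  ts <- ThermalSeries(rep(34, length(t)), t)
  expect_warning(tv <- variabilitySequence(ts), "constant")
  expect_true(all(signalValues(tv) == 0.5))
  expect_equal(seriesStatus(tv), "constant")
})

test_that("extractThermal composes filtering and scaling", {
  ts <- simulateThermal(trendSlope = -0.03, seed = 5L)
  tv <- extractThermal(ts)
  expect_s4_class(tv, "ThermalVariability")
  expect_true(all(signalValues(tv) >= 0 & signalValues(tv) <= 1))
  # planted cooling survives breathing removal
  expect_lt(filteredTemps(tv)[length(filteredTemps(tv))] -
              filteredTemps(tv)[1], -0.3)
})

test_that("removeBreathing rejects records too short for the filter order", {
  t <- seq(0, 5, by = 0.5)
  ts <- ThermalSeries(rep(34, length(t)) + sin(t), t)
  expect_error(removeBreathing(ts), "samples")
})
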