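test_that("spatialEntropy matches closed forms", {
  expect_equal(spatialEntropy(matrix(117, 8, 8)), 0)
  expect_equal(spatialEntropy(matrix(c(10, 10, 20, 30), 2, 2)), 1.5)
  # half 0s, half 255s -> 1 bit
  expect_equal(spatialEntropy(matrix(c(0, 255), 4, 4)), 1)
  # 4 equally frequent levels -> 2 bits
  expect_equal(spatialEntropy(matrix(c(1, 64, 128, 200), 2, 2)), 2)
  expect_error(spatialEntropy(matrix(-1, 2, 2)), "0..255")
  expect_error(spatialEntropy(1:4), "matrix")
})

test_that("coarse binning pools neighbouring grey levels", {
  # 0 and 1 fall in the same bin at nbins = 128 (bin width 2)
  f <- matrix(c(0, 1), 2, 2)
  expect_equal(spatialEntropy(f, nbins = 256L), 1)
  expect_equal(spatialEntropy(f, nbins = 128L), 0)
})

test_that("estimateRawBvp reduces frames by the requested method", {
  f <- list(matrix(10L, 2, 2), matrix(c(10L, 20L, 30L, 40L), 2, 2),
            matrix(200L, 2, 2))
  fs <- FrameStack(f, c(0, 0.1, 0.2))
  ent <- estimateRawBvp(fs, method = "entropy")
  expect_equal(signalValues(ent), c(0, -2, 0))
  mi <- estimateRawBvp(fs, method = "mean_intensity")
  expect_equal(signalValues(mi), c(10, 25, 200))
})

test_that("resampleUniform reproduces a smooth waveform between frames", {
  ts <- seq(0, 5, by = 1 / 30)
  sig <- new("EntropySignal", values = sin(2 * pi * 1.2 * ts),
             timestamps = ts)
  up <- resampleUniform(sig, rate = 256)
  expect_equal(sampleRate(up), 256)
  tt <- timestamps(up)
  inner <- tt > 0.2 & tt < 4.8
  expect_lt(max(abs(signalValues(up)[inner] - sin(2 * pi * 1.2 * tt[inner]))),
            1e-3)
  expect_error(resampleUniform(sig, rate = 50), "twice")
})

test_that("equalizeAmplitude removes slow baseline exactly for constants", {
  b <- new("BvpSignal", values = rep(3.7, 100), rate = 20, t0 = 0)
  eq <- equalizeAmplitude(b, windowS = 1)
  expect_equal(signalValues(eq), rep(0, 100))
  expect_error(equalizeAmplitude(b, windowS = 10), "shorter")
})

test_that("equalizeAmplitude suppresses a linear trend in the interior", {
  x <- seq(0, 10, length.out = 200)
  b <- new("BvpSignal", values = 5 * x, rate = 20, t0 = 0)
  # windowS chosen to give an odd window (k = 19): symmetric around the
  # centre sample, so a line cancels exactly in the interior
  eq <- equalizeAmplitude(b, windowS = 0.95)
  expect_lt(max(abs(signalValues(eq)[20:180])), 1e-9)
  # an even window is asymmetric by half a sample: small uniform offset
  eq2 <- equalizeAmplitude(b, windowS = 1)
  off <- signalValues(eq2)[20:180]
  expect_lt(diff(range(off)), 1e-9)
})

test_that("detectPPIntervals finds planted peaks and breaks ties early", {
  # explicit peaks at samples 1, 11, 21 of a 10 Hz signal
  v <- rep(0, 30); v[c(1, 11, 21)] <- 1
  b <- new("BvpSignal", values = v, rate = 10, t0 = 0)
  pp <- detectPPIntervals(b, windowS = 0.5, validityFilter = FALSE)
  expect_equal(peakTimes(pp), c(0, 1, 2))
  expect_equal(ppIntervals(pp), c(1000, 1000))
  # a plateau: the earlier of two equal samples wins
  v2 <- c(0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0)
  b2 <- new("BvpSignal", values = v2, rate = 10, t0 = 0)
  pp2 <- detectPPIntervals(b2, windowS = 0.5, validityFilter = FALSE)
  expect_equal(peakTimes(pp2), c(0.1, 1.1))
})

test_that("validity filter flags non-physiologic intervals", {
  v <- rep(0, 40); v[c(1, 4, 11, 31)] <- 1   # gaps 300, 700, 2000 ms
  b <- new("BvpSignal", values = v, rate = 10, t0 = 0)
  pp <- detectPPIntervals(b, windowS = 0.5, validityFilter = TRUE)
  expect_equal(validIntervals(pp), ppIntervals(pp)[ppIntervals(pp) >= 500 &
                                                     ppIntervals(pp) <= 1250])
})

test_that("flat windows yield an empty series with a warning", {
  b <- new("BvpSignal", values = rep(0, 100), rate = 10, t0 = 0)
  expect_warning(pp <- detectPPIntervals(b), "fewer than 2")
  expect_equal(seriesStatus(pp), "too_few_peaks")
  expect_length(ppIntervals(pp), 0)
})

test_that("extractPPG recovers planted PP intervals from rendered frames", {
  rr <- generateRR(meanRR = 850, sdppTarget = 30, rmssdTarget = 25,
                   durationS = 20, seed = 42L)
  stack <- renderPpgFrames(rr, fps = 30, seed = 42L)
  res <- extractPPG(stack)
  expect_s4_class(res$bvp, "BvpSignal")
  # the edge guard drops peaks near the record ends, so match by nearest
  # peak time rather than by position
  pt <- peakTimes(rr)
  rt <- peakTimes(res$pp)
  errs <- numeric(0)
  for (j in seq_len(length(pt) - 1L)) {
    a <- rt[which.min(abs(rt - pt[j]))]
    b <- rt[which.min(abs(rt - pt[j + 1L]))]
    if (abs(a - pt[j]) < 0.1 && abs(b - pt[j + 1L]) < 0.1 && b > a)
      errs <- c(errs, abs((b - a) * 1000 - ppIntervals(rr)[j]))
  }
  expect_gt(length(errs), 15)
  expect_lt(mean(errs), 5)
})

test_that("mean-intensity baseline misses spread-modulated pulsatility", {
  rr <- generateRR(meanRR = 850, sdppTarget = 20, rmssdTarget = 15,
                   durationS = 20, seed = 7L)
  stack <- renderPpgFrames(rr, fps = 30, seed = 7L, mode = "entropy")
  ent <- estimateRawBvp(stack, method = "entropy")
  mi <- estimateRawBvp(stack, method = "mean_intensity")
  # entropy channel carries the modulation; the spatial mean barely moves
  expect_gt(sd(signalValues(ent)) / abs(mean(signalValues(ent))),
            10 * sd(signalValues(mi)) / abs(mean(signalValues(mi))))
})
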