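test_that("generateRR hits its calibration targets on long records", {
  rr <- generateRR(meanRR = 850, sdppTarget = 30, rmssdTarget = 25,
                   durationS = 600, seed = 17L)
  iv <- ppIntervals(rr)
  expect_equal(mean(iv), 850, tolerance = 0.02)
  expect_equal(sd(iv), 30, tolerance = 0.15)
  expect_equal(sqrt(mean(diff(iv)^2)), 25, tolerance = 0.15)
  expect_true(all(iv >= 500 & iv <= 1250))
})

test_that("generateRR is deterministic and validates its inputs", {
  a <- generateRR(seed = 2L); b <- generateRR(seed = 2L)
  expect_identical(ppIntervals(a), ppIntervals(b))
  expect_error(generateRR(meanRR = 400), "500")
  expect_error(generateRR(sdppTarget = 10, rmssdTarget = 40), "infeasible")
})

test_that("renderPpgFrames plants entropy minima at beat times", {
  rr <- generateRR(meanRR = 800, sdppTarget = 10, rmssdTarget = 8, seed = 4L)
  stack <- renderPpgFrames(rr, fps = 30, seed = 4L)
  expect_s4_class(stack, "FrameStack")
  ent <- estimateRawBvp(stack)
  # negated entropy should peak (entropy dip) near each planted beat
  bvp <- resampleUniform(ent)
  eq <- equalizeAmplitude(bvp)
  tt <- timestamps(eq)
  atBeat <- vapply(peakTimes(rr), function(b)
    signalValues(eq)[which.min(abs(tt - b))], numeric(1))
  expect_gt(mean(atBeat), quantile(signalValues(eq), 0.75))
  expect_error(renderPpgFrames(rr, fps = 10), "fps")
  expect_error(renderPpgFrames(rr, modulationDepth = 0), "modulationDepth")
})

test_that("simulateThermal produces strictly increasing jittered timestamps", {
  ts <- simulateThermal(seed = 6L)
  expect_true(all(diff(timestamps(ts)) > 0))
  expect_equal(length(signalValues(ts)), length(timestamps(ts)))
  expect_error(simulateThermal(breathingHz = 0.05), "breathing band")
  expect_error(simulateThermal(durationS = 5), "10")
})

test_that("generateCohort emits a consistent protocol-shaped dataset", {
  co <- generateCohort(nParticipants = 4L, seed = 13L, renderFrames = FALSE)
  expect_length(co$inputs, 24)
  expect_equal(nrow(co$scores), 24)
  expect_true(all(co$scores$vas >= 0 & co$scores$vas <= 10))
  expect_equal(sort(unique(co$truth$truth)), c("NoStress", "Stress"))
  expect_true(all(co$truth$truth[co$truth$session_id %in%
                                   c("Se", "Sh", "Me", "Mh")] == "Stress"))
  co2 <- generateCohort(nParticipants = 4L, seed = 13L, renderFrames = FALSE)
  expect_identical(co$scores, co2$scores)
  expect_error(generateCohort(rmssdEffect = 1.2), "fractional")
  expect_error(generateCohort(nParticipants = 2L), "3")
})

test_that("planted stress suppresses RMSSD and cools the nose on average", {
  co <- generateCohort(nParticipants = 8L, seed = 19L, renderFrames = FALSE)
  w <- suppressWarnings(suppressMessages(
    extractCohortWindows(co, usePlantedPP = TRUE)))
  stressIdx <- co$truth$truth == "Stress"
  rmssd <- vapply(w, function(x) prvFeatures(x@pp)[["rmssd"]], numeric(1))
  td <- vapply(w, function(x) thermalFeatures(x@tv)[["td"]], numeric(1))
  expect_lt(mean(rmssd[stressIdx]), mean(rmssd[!stressIdx]))
  expect_lt(mean(td[stressIdx]), mean(td[!stressIdx]))
})

test_that("extractCohortWindows uses planted PP when frames are absent", {
  co <- generateCohort(nParticipants = 3L, seed = 23L, renderFrames = FALSE)
  w <- suppressWarnings(suppressMessages(extractCohortWindows(co)))
  expect_identical(ppIntervals(w[[1]]@pp), ppIntervals(co$inputs[[1]]$rr))
  expect_s4_class(w[[1]]@tv, "ThermalVariability")
})
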