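smallCohort <- function(seed = 31L, n = 5L, ...) {
  co <- generateCohort(nParticipants = n, seed = seed, renderFrames = FALSE,
                       ...)
  w <- suppressWarnings(suppressMessages(
    extractCohortWindows(co, usePlantedPP = TRUE)))
  list(cohort = co,
       windows = labelWindows(w, assignLabels(co$scores, strategy = "L1")))
}

test_that("encodeLowLevel produces fixed-length vectors per modality", {
  rr <- generateRR(durationS = 20, seed = 12L)
  tv <- extractThermal(simulateThermal(seed = 12L))
  w <- MeasurementWindow("P01", "Se", pp = rr, tv = tv, vas = 4)
  expect_length(encodeLowLevel(w, "multimodal"), 60)
  expect_length(encodeLowLevel(w, "ppg_only"), 40)
  expect_length(encodeLowLevel(w, "thermal_only"), 20)
  # an unusable PP series means exclusion, not zero-filling
  empty <- new("PPIntervalSeries", intervals = numeric(0),
               peakTimes = numeric(0), valid = logical(0),
               status = "too_few_peaks")
  we <- MeasurementWindow("P01", "Se", pp = empty, tv = tv, vas = 4)
  expect_null(encodeLowLevel(we, "multimodal"))
  expect_length(encodeLowLevel(we, "thermal_only"), 20)
})

test_that("buildFeatureMatrix drops unusable windows with a message", {
  s <- smallCohort()
  w <- s$windows
  empty <- new("PPIntervalSeries", intervals = numeric(0),
               peakTimes = numeric(0), valid = logical(0),
               status = "too_few_peaks")
  w[[1]]@pp <- empty
  expect_message(X <- buildFeatureMatrix(w, "multimodal", "low"), "excluded")
  expect_equal(nrow(X), length(w) - 1L)
  expect_equal(attr(X, "kept"), 2:length(w))
})

test_that("fitNN is deterministic in the seed and separates blobs", {
  set.seed(1)
  X <- rbind(matrix(rnorm(60, -2), 30), matrix(rnorm(60, 2), 30))
  y <- rep(c(0L, 1L), each = 30)
  m1 <- fitNN(X, y, hiddenSize = 10L, seed = 5L, epochs = 20L)
  m2 <- fitNN(X, y, hiddenSize = 10L, seed = 5L, epochs = 20L)
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@b2, m2@b2)
  m3 <- fitNN(X, y, hiddenSize = 10L, seed = 6L, epochs = 20L)
  expect_false(identical(m1@W1, m3@W1))
  expect_equal(predict(m1, X), y)
  p <- predict(m1, X, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fitNN(X, rep(0L, 60), hiddenSize = 4L), "single class")
})

test_that("knn1Classify is exact 1-NN with earliest-index tie-break", {
  trainX <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
  trainY <- c(0L, 1L, 0L)
  expect_equal(knn1Classify(trainX, trainY,
                            matrix(c(0.1, 0.1, 1.9, 1.9), 2, 2,
                                   byrow = TRUE)),
               c(0L, 0L))
  # equidistant between rows 1 (label 0) and 2 (label 1): earliest wins
  expect_equal(knn1Classify(trainX, trainY,
                            matrix(c(0.5, 0.5), 1, 2)), 0L)
  expect_error(knn1Classify(trainX, trainY, matrix(0, 1, 3)), "mismatch")
})

test_that("foldMacroF1 matches a hand-computed confusion", {
  truth <- c(0, 0, 0, 1, 1)
  pred <- c(0, 0, 1, 1, 0)
  # class 0: tp 2 fp 1 fn 1 -> 2/3; class 1: tp 1 fp 1 fn 1 -> 0.5
  expect_equal(pulseTherm:::foldMacroF1(truth, pred), mean(c(2 / 3, 0.5)))
  # a fold where one class never occurs in truth or prediction is undefined
  expect_true(is.na(pulseTherm:::foldMacroF1(c(0, 0), c(0, 0))))
  # total misclassification is defined and zero
  expect_equal(pulseTherm:::foldMacroF1(c(0, 0, 1), c(1, 1, 0)), 0)
})

test_that("losoCv folds partition by participant and accumulate confusion", {
  s <- smallCohort()
  cv <- suppressMessages(losoCv(s$windows, model = "knn",
                                modality = "multimodal", seed = 2L))
  expect_s4_class(cv, "CvReport")
  expect_equal(sort(names(foldAccuracies(cv))), sprintf("P%02d", 1:5))
  expect_equal(sum(confusionMatrix(cv)), length(s$windows))
  expect_true(all(foldAccuracies(cv) >= 0 & foldAccuracies(cv) <= 1))
})

test_that("losoCv is deterministic and honours session exclusion", {
  s <- smallCohort()
  a <- suppressMessages(losoCv(s$windows, "nn1", "ppg_only", seed = 3L,
                               epochs = 10L))
  b <- suppressMessages(losoCv(s$windows, "nn1", "ppg_only", seed = 3L,
                               epochs = 10L))
  expect_identical(foldAccuracies(a), foldAccuracies(b))
  ex <- suppressMessages(losoCv(s$windows, "knn", "multimodal",
                                excludeSessions = "Rest1"))
  expect_equal(sum(confusionMatrix(ex)), length(s$windows) - 5L)
  expect_error(losoCv(s$windows[1:6], "knn"), "3 participants")
})

test_that("labelWindows joins by participant and session", {
  s <- smallCohort()
  expect_true(all(vapply(s$windows, function(w)
    w@label %in% c("NoStress", "Stress"), logical(1))))
  bad <- s$cohort$scores[-1, ]
  expect_error(labelWindows(s$windows,
                            assignLabels(bad, "L4")), "no label")
})
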