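# Classifiers and leave-one-subject-out evaluation.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Fixed-length low-level encoding of a measurement window
#'
#' Neural networks need fixed-width inputs, but a 20 s window yields a
#' variable number of PP intervals. The valid PP intervals are linearly
#' interpolated over the beat index onto `ppLen` equally spaced points
#' (interpolation rather than zero-padding avoids magnitude artifacts); the
#' thermal variability sequence is truncated or edge-padded to `tvLen`
#' points. The multimodal encoding is their concatenation.
#'
#' @param window a [MeasurementWindow-class].
#' @param modality `"multimodal"`, `"ppg_only"` or `"thermal_only"`.
#' @param ppLen encoded PP length (default 40).
#' @param tvLen encoded thermal length (default 20).
#' @return Numeric vector of length `ppLen`, `tvLen` or `ppLen + tvLen`, or
#'   `NULL` when a required modality is unusable (empty PP series or missing
#'   sequence), in which case the window must be excluded.
#' @export
encodeLowLevel <- function(window, modality = c("multimodal", "ppg_only",
                           "thermal_only"), ppLen = 40L, tvLen = 20L) {
  modality <- match.arg(modality)
  ppPart <- NULL
  if (modality != "thermal_only") {
    if (is.null(window@pp)) return(NULL)
    iv <- validIntervals(window@pp)
    if (length(iv) < 2L) return(NULL)
    ppPart <- stats::approx(seq_along(iv), iv,
                            xout = seq(1, length(iv), length.out = ppLen))$y
  }
  tvPart <- NULL
  if (modality != "ppg_only") {
    if (is.null(window@tv)) return(NULL)
    v <- window@tv@values
    tvPart <- if (length(v) >= tvLen) v[seq_len(tvLen)]
              else c(v, rep(v[length(v)], tvLen - length(v)))
  }
  c(ppPart, tvPart)
}

#' Encode a set of windows into a feature matrix
#'
#' Builds the design matrix for classification at either feature level.
#' `level = "low"` uses [encodeLowLevel()]; `level = "high"` uses the 9 (or
#' 6/3) engineered features from [highLevelFeatures()]. Windows whose
#' encoding is unusable (empty PP series, missing features) are dropped with
#' a message; the returned matrix carries the kept windows' indices in
#' `attr(, "kept")`.
#'
#' @param windows list of [MeasurementWindow-class].
#' @param modality `"multimodal"`, `"ppg_only"` or `"thermal_only"`.
#' @param level `"low"` or `"high"`.
#' @param ppLen,tvLen low-level encoding lengths.
#' @return Numeric matrix, rows = usable windows.
#' @export
buildFeatureMatrix <- function(windows, modality = c("multimodal", "ppg_only",
                               "thermal_only"), level = c("low", "high"),
                               ppLen = 40L, tvLen = 20L) {
  modality <- match.arg(modality)
  level <- match.arg(level)
  rows <- lapply(windows, function(w) {
    r <- if (level == "low")
      encodeLowLevel(w, modality, ppLen = ppLen, tvLen = tvLen)
    else highLevelFeatures(w, modality)
    if (is.null(r) || anyNA(r)) NULL else r
  })
  kept <- which(!vapply(rows, is.null, logical(1L)))
  if (length(kept) < length(windows))
    message(length(windows) - length(kept),
            " window(s) excluded: unusable ", level, "-level ", modality,
            " encoding")
  X <- do.call(rbind, rows[kept])
  attr(X, "kept") <- kept
  X
}

#' Train a single-hidden-layer sigmoid network
#'
#' Z-scores the features by the training-set mean and SD (stored in the model
#' and reused verbatim on test data), then trains a single-hidden-layer
#' network with sigmoid hidden units and a single sigmoid output under binary
#' cross-entropy, by plain per-sample stochastic gradient descent: fixed
#' learning rate 0.5, 100 epochs, samples reshuffled every epoch. Weight
#' initialization is uniform(-0.1, 0.1). All randomness derives from `seed`,
#' so training is bit-reproducible.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels: factor/character with levels NoStress/Stress, or 0/1.
#' @param hiddenSize hidden nodes, 80 (NN1) or 260 (NN2) in the standard
#'   configurations.
#' @param seed integer seed for init and shuffling.
#' @param lr learning rate (default 0.5).
#' @param epochs training epochs (default 100).
#' @return An [NNModel-class].
#' @export
fitNN <- function(X, y, hiddenSize = 80L, seed = 1L, lr = 0.5, epochs = 100L) {
  X <- as.matrix(X)
  y01 <- labelTo01(y)
  if (length(unique(y01)) < 2L) stop("training set has a single class")
  if (min(table(y01)) < 2L) stop("need >= 2 training windows per class")
  mu <- colMeans(X)
  sigma <- apply(X, 2L, sd)
  sigma[sigma == 0] <- 1
  Xz <- sweep(sweep(X, 2L, mu), 2L, sigma, "/")
  d <- ncol(X); h <- as.integer(hiddenSize); n <- nrow(X)
  fit <- withSeed(seed, {
    W1 <- matrix(runif(d * h, -0.1, 0.1), d, h)
    b1 <- runif(h, -0.1, 0.1)
    W2 <- runif(h, -0.1, 0.1)
    b2 <- runif(1L, -0.1, 0.1)
    ord <- vapply(seq_len(epochs), function(e) sample.int(n),
                  integer(n))
    nn_sgd_train(Xz, as.integer(y01), W1, b1, W2, b2, ord, lr)
  })
  new("NNModel", W1 = fit$W1, b1 = as.numeric(fit$b1),
      W2 = as.numeric(fit$W2), b2 = as.numeric(fit$b2),
      mu = mu, sigma = sigma, hiddenSize = h, seed = as.integer(seed))
}

labelTo01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("NoStress", "Stress")))
      stop("character labels must be NoStress/Stress")
    as.integer(y == "Stress")
  } else as.integer(y)
}

#' @describeIn fitNN Predict stress probabilities or classes; the decision
#'   threshold is 0.5.
#' @param object an [NNModel-class].
#' @param newdata numeric matrix of features (raw scale; the model applies
#'   its stored training z-scoring).
#' @param type `"class"` (0/1) or `"prob"`.
#' @export
setMethod("predict", "NNModel", function(object, newdata,
                                         type = c("class", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xz <- sweep(sweep(X, 2L, object@mu), 2L, object@sigma, "/")
  p <- nn_forward(Xz, object@W1, object@b1, object@W2, object@b2)
  if (type == "prob") p else as.integer(p >= 0.5)
})

#' 1-nearest-neighbour classification
#'
#' Assigns each test row the label of its Euclidean-nearest training row.
#' Features are z-scored by the training-set mean/SD before distances are
#' computed; distance ties are broken toward the earliest training index.
#'
#' @param trainX,trainY training features and labels.
#' @param testX test features (same columns as `trainX`).
#' @return Integer vector of 0/1 predictions, one per test row.
#' @export
knn1Classify <- function(trainX, trainY, testX) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  if (ncol(trainX) != ncol(testX)) stop("feature dimension mismatch")
  if (nrow(trainX) == 0L) stop("empty training set")
  y <- labelTo01(trainY)
  mu <- colMeans(trainX)
  sigma <- apply(trainX, 2L, sd)
  sigma[sigma == 0] <- 1
  Tz <- sweep(sweep(trainX, 2L, mu), 2L, sigma, "/")
  Qz <- sweep(sweep(testX, 2L, mu), 2L, sigma, "/")
  # squared distances via the expansion |t|^2 - 2 q.t; which.min takes the
  # earliest index on ties
  tn <- rowSums(Tz^2)
  D <- outer(rep(1, nrow(Qz)), tn) - 2 * Qz %*% t(Tz)
  y[apply(D, 1L, which.min)]
}

foldMacroF1 <- function(truth, pred) {
  f1s <- vapply(c(0L, 1L), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  if (anyNA(f1s)) NA_real_ else mean(f1s)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per participant: the model is trained on all other participants'
#' windows and tested on the held-out participant, so reported accuracy
#' measures generalization to unseen people. Reports per-fold accuracies,
#' their mean/SD, the confusion matrix accumulated (summed) over folds, and
#' the mean per-fold macro F1 (folds where F1 is undefined are skipped with
#' a message).
#'
#' Windows must carry labels (see [assignLabels()] and
#' [labelWindows()]). Named sessions can be excluded (e.g. `"Rest1"`, whose
#' thermal recordings are prone to entering-the-room temperature artifacts).
#'
#' @param windows list of labelled [MeasurementWindow-class] objects from at
#'   least 3 participants.
#' @param model `"nn1"` (80 hidden), `"nn2"` (260 hidden) or `"knn"` (1-NN).
#' @param modality `"multimodal"`, `"ppg_only"` or `"thermal_only"`.
#' @param level `"low"` (PP/thermal sequences; the NN default) or `"high"`
#'   (the 9 engineered features; the kNN default).
#' @param seed integer seed; each fold trains with a seed derived from it.
#' @param excludeSessions character vector of session ids to drop, or `NULL`.
#' @param ppLen,tvLen low-level encoding lengths.
#' @param lr,epochs NN training hyperparameters.
#' @return A [CvReport-class].
#' @export
losoCv <- function(windows, model = c("nn1", "nn2", "knn"),
                   modality = c("multimodal", "ppg_only", "thermal_only"),
                   level = NULL, seed = 1L, excludeSessions = NULL,
                   ppLen = 40L, tvLen = 20L, lr = 0.5, epochs = 100L) {
  model <- match.arg(model)
  modality <- match.arg(modality)
  if (is.null(level)) level <- if (model == "knn") "high" else "low"
  level <- match.arg(level, c("low", "high"))
  if (!is.null(excludeSessions))
    windows <- Filter(function(w) !(w@sessionId %in% excludeSessions), windows)
  labs <- vapply(windows, function(w) w@label, character(1L))
  if (anyNA(labs)) stop("all windows must be labelled before LOSO")
  pids <- vapply(windows, function(w) w@participantId, character(1L))
  if (length(unique(pids)) < 3L) stop("need at least 3 participants")

  X <- buildFeatureMatrix(windows, modality, level, ppLen = ppLen,
                          tvLen = tvLen)
  kept <- attr(X, "kept")
  y <- labelTo01(labs[kept])
  pid <- pids[kept]
  folds <- unique(pid)
  acc <- numeric(0)
  f1s <- numeric(0)
  conf <- matrix(0, 2L, 2L,
                 dimnames = list(truth = c("NoStress", "Stress"),
                                 pred = c("NoStress", "Stress")))
  for (i in seq_along(folds)) {
    te <- pid == folds[i]
    if (!any(te)) { warning("fold with zero windows skipped: ", folds[i]);
                    next }
    pred <- if (model == "knn") {
      knn1Classify(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
    } else {
      hs <- if (model == "nn1") 80L else 260L
      m <- fitNN(X[!te, , drop = FALSE], y[!te], hiddenSize = hs,
                 seed = as.integer(seed) + i, lr = lr, epochs = epochs)
      predict(m, X[te, , drop = FALSE])
    }
    truth <- y[te]
    a <- mean(pred == truth)
    acc <- c(acc, structure(a, names = folds[i]))
    for (ti in 0:1) for (pi in 0:1)
      conf[ti + 1L, pi + 1L] <- conf[ti + 1L, pi + 1L] +
        sum(truth == ti & pred == pi)
    f1 <- foldMacroF1(truth, pred)
    if (is.na(f1)) message("fold ", folds[i], ": macro F1 undefined, skipped")
    else f1s <- c(f1s, f1)
  }
  new("CvReport", foldAccuracy = acc, confusion = conf,
      meanF1 = if (length(f1s)) mean(f1s) else NA_real_,
      model = model, modality = modality, level = level)
}

#' Attach labels from a labelled score table to windows
#'
#' Joins the output of [assignLabels()] back onto a list of
#' [MeasurementWindow-class] objects by participant and session id.
#'
#' @param windows list of [MeasurementWindow-class].
#' @param labelled data.frame from [assignLabels()].
#' @return The windows with `label` slots set.
#' @export
labelWindows <- function(windows, labelled) {
  key <- paste(labelled$participant_id, labelled$session_id)
  lapply(windows, function(w) {
    i <- match(paste(w@participantId, w@sessionId), key)
    if (is.na(i)) stop("no label for window ", w@participantId, "/",
                       w@sessionId)
    w@label <- as.character(labelled$label[i])
    w
  })
}
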