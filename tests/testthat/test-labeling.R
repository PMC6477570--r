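test_that("normalizeScores rescales each participant to [0,1]", {
  df <- data.frame(participant_id = rep(c("P1", "P2"), each = 3),
                   session_id = rep(c("a", "b", "c"), 2),
                   vas = c(1, 3, 5, 2, 2.5, 3))
  out <- normalizeScores(df)
  expect_equal(out$normalized, c(0, 0.5, 1, 0, 0.5, 1))
  bad <- data.frame(participant_id = c("P1", "P1"), session_id = c("a", "b"),
                    vas = c(4, 4))
  expect_error(normalizeScores(bad), "degenerate")
  expect_error(normalizeScores(transform(df, vas = vas + 9)), "0,10")
})

test_that("kmeans1d matches the exhaustive contiguous-split oracle", {
  oracleSse <- function(x, k) {
    x <- sort(x); n <- length(x)
    best <- Inf
    splits <- utils::combn(n - 1L, k - 1L)
    for (c in seq_len(ncol(splits))) {
      b <- c(0L, splits[, c], n)
      sse <- 0
      for (m in seq_len(k)) {
        seg <- x[(b[m] + 1L):b[m + 1L]]
        sse <- sse + sum((seg - mean(seg))^2)
      }
      best <- min(best, sse)
    }
    best
  }
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    k <- sample(2:3, 1)
    x <- round(runif(n), 3)
    if (length(unique(x)) < k) next
    expect_equal(kmeans1d(x, k)$sse, oracleSse(x, k), tolerance = 1e-9)
  }
})

test_that("kmeans1d is deterministic with ascending centers", {
  set.seed(5)
  x <- runif(40)
  a <- kmeans1d(x, 3); b <- kmeans1d(x, 3)
  expect_identical(a, b)
  expect_true(all(diff(a$centers) > 0))
  expect_error(kmeans1d(c(1, 1, 1), 2), "distinct")
})

test_that("kmeans1d recovers well-separated trimodal groups", {
  set.seed(6)
  truth <- rep(1:3, each = 30)
  x <- c(rnorm(30, 0.1, 0.03), rnorm(30, 0.5, 0.03), rnorm(30, 0.9, 0.03))
  cl <- kmeans1d(x, 3)$cluster
  expect_gte(mean(cl == truth), 0.95)
})

test_that("assignLabels implements the four strategies coherently", {
  set.seed(7)
  df <- data.frame(participant_id = rep(sprintf("P%02d", 1:8), each = 6),
                   session_id = rep(letters[1:6], 8),
                   vas = round(runif(48, 0, 10), 2))
  l1 <- assignLabels(df, "L1"); l2 <- assignLabels(df, "L2")
  l3 <- assignLabels(df, "L3"); l4 <- assignLabels(df, "L4")
  # L1 Stress (clusters 2,3) contains L2 Stress (cluster 3 only)
  expect_true(all(which(l2$label == "Stress") %in%
                    which(l1$label == "Stress")))
  expect_equal(sort(unique(l3$cluster)), 1:2)
  expect_true(all(levels(l1$label) == c("NoStress", "Stress")))
  # L4 raw threshold at one third of the 10-cm scale
  expect_equal(unname(l4$label[df$vas < 10 / 3] == "NoStress"),
               rep(TRUE, sum(df$vas < 10 / 3)))
  expect_true(all(l4$label[df$vas >= 10 / 3] == "Stress"))
})

test_that("L4 boundary sits exactly at 10/3 on the raw scale", {
  df <- data.frame(participant_id = rep("P1", 4), session_id = letters[1:4],
                   vas = c(3.333, 3.334, 0, 10))
  l4 <- assignLabels(df, "L4")
  expect_equal(as.character(l4$label),
               c("NoStress", "Stress", "NoStress", "Stress"))
})
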