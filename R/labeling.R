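#' Per-participant min-max normalization of VAS stress scores
#'
#' Self-reported stress scores vary strongly between people in both offset
#' and range. Each participant's scores are min-max scaled to \[0,1\] using
#' that participant's own minimum and maximum over all sessions, so ranges
#' become comparable across people while within-participant rank order is
#' preserved exactly.
#'
#' @param scores data.frame with columns `participant_id`, `session_id`,
#'   `vas` (numeric in \[0,10\]). Every participant needs at least 2 sessions
#'   and a non-degenerate score range.
#' @return The input data.frame with an added `normalized` column in \[0,1\].
#' @examples
#' df <- data.frame(participant_id = "P1", session_id = c("a", "b", "c"),
#'                  vas = c(1, 3, 5))
#' normalizeScores(df)$normalized  # 0, 0.5, 1
#' @export
normalizeScores <- function(scores) {
  stopifnot(all(c("participant_id", "session_id", "vas") %in% names(scores)))
  if (any(scores$vas < 0 | scores$vas > 10))
    stop("vas scores must lie in [0,10]")
  norm <- ave(scores$vas, scores$participant_id, FUN = function(v) {
    if (length(v) < 2L) stop("participant with fewer than 2 sessions")
    r <- range(v)
    if (r[2L] <= r[1L]) return(rep(NA_real_, length(v)))
    (v - r[1L]) / (r[2L] - r[1L])
  })
  if (anyNA(norm)) {
    bad <- unique(scores$participant_id[is.na(norm)])
    stop("degenerate score range (max = min) for participant(s): ",
         paste(bad, collapse = ", "))
  }
  scores$normalized <- norm
  scores
}

#' Exact 1-D k-means clustering
#'
#' Globally optimal k-means partition of scalar values. An optimal 1-D
#' k-means solution is contiguous in sorted order, so the minimum
#' within-cluster sum of squares is found exactly by dynamic programming over
#' contiguous breakpoints; there is no random initialization and the result
#' is deterministic. Clusters are indexed 1..k by ascending centroid.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of clusters (>= 2).
#' @return List with `cluster` (integer assignment per input value),
#'   `centers` (ascending centroids) and `sse` (total within-cluster sum of
#'   squares).
#' @export
kmeans1d <- function(values, k) {
  if (k < 2L) stop("k must be >= 2")
  n <- length(values)
  if (length(unique(values)) < k)
    stop("need at least k distinct values")
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # cost of cluster spanning sorted positions i..j
  cost <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  D <- matrix(Inf, k, n)     # D[m, j]: best SSE of first j points in m clusters
  B <- matrix(0L, k, n)      # argmin split
  for (j in 1:n) D[1L, j] <- cost(1L, j)
  if (k > 1L) for (m in 2:k) {
    for (j in m:n) {
      best <- Inf; arg <- m
      for (i in m:j) {
        v <- D[m - 1L, i - 1L] + cost(i, j)
        if (v < best) { best <- v; arg <- i }
      }
      D[m, j] <- best; B[m, j] <- arg
    }
  }
  # backtrack
  bounds <- integer(k + 1L); bounds[k + 1L] <- n
  j <- n
  for (m in k:2) {
    i <- B[m, j]
    bounds[m] <- i - 1L
    j <- i - 1L
  }
  bounds[1L] <- 0L
  clSorted <- integer(n)
  centers <- numeric(k)
  for (m in 1:k) {
    idx <- (bounds[m] + 1L):bounds[m + 1L]
    clSorted[idx] <- m
    centers[m] <- mean(x[idx])
  }
  cluster <- integer(n)
  cluster[ord] <- clSorted
  list(cluster = cluster, centers = centers, sse = D[k, n])
}

#' Binary stress labels from self-report scores
#'
#' Produces Stress / No-Stress labels under four strategies:
#' \describe{
#'   \item{L1}{exact k-means (k=3) on the pooled normalized scores; the
#'     lowest cluster ("none or low") is NoStress, the "moderate" and
#'     "very high" clusters are Stress. The package's main strategy.}
#'   \item{L2}{k=3, but the two lowest clusters form NoStress.}
#'   \item{L3}{k-means with k=2 on the normalized scores.}
#'   \item{L4}{fixed threshold on the raw VAS scale: the 10 cm scale divided
#'     into three equal sections, scores below 10/3 (printed 3.334) are
#'     NoStress.}
#' }
#' K-means pooling is joint over all participants' normalized scores.
#'
#' @param scores data.frame as for [normalizeScores()]; a `normalized`
#'   column is added if absent (L4 uses the raw `vas` column).
#' @param strategy one of `"L1"`, `"L2"`, `"L3"`, `"L4"`.
#' @return The input data.frame with columns `normalized`, `cluster`
#'   (`NA` for L4) and `label` (factor, levels `NoStress`, `Stress`).
#' @export
assignLabels <- function(scores, strategy = c("L1", "L2", "L3", "L4")) {
  strategy <- match.arg(strategy)
  if (!"normalized" %in% names(scores)) scores <- normalizeScores(scores)
  if (strategy == "L4") {
    scores$cluster <- NA_integer_
    scores$label <- factor(ifelse(scores$vas < 10 / 3, "NoStress", "Stress"),
                           levels = c("NoStress", "Stress"))
  } else {
    k <- if (strategy == "L3") 2L else 3L
    km <- kmeans1d(scores$normalized, k)
    scores$cluster <- km$cluster
    noStress <- switch(strategy, L1 = 1L, L2 = c(1L, 2L), L3 = 1L)
    scores$label <- factor(ifelse(km$cluster %in% noStress, "NoStress",
                                  "Stress"),
                           levels = c("NoStress", "Stress"))
  }
  scores$strategy <- strategy
  scores
}
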