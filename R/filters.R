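# Zero-phase IIR filtering and Welch PSD estimation.
#
# r-signal provides filter design (butter) and a filtfilt without edge
# padding; on 20 s windows with a 0.08 Hz cutoff the un-padded edge transient
# would swamp the signal, so the forward-backward pass here uses odd
# (point-reflected) extension plus steady-state initial conditions, the
# convention of mainstream DSP toolboxes.

#' @importFrom signal butter
NULL

# Steady-state filter state for a unit-amplitude step input (direct form II
# transposed), obtained from the companion-matrix linear system.
lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1L]
  b <- c(b, rep(0, n - length(b))) / 1
  if (n == 1L) return(numeric(0))
  comp <- rbind(-a[-1L], cbind(diag(1, n - 2L, n - 2L),
                               rep(0, n - 2L)))
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

# Linear filter with explicit initial state (direct form II transposed).
dfilt <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1L]; a <- a / a[1L]
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  .Call(`_pulseTherm_df2t_filter`, as.numeric(b), as.numeric(a),
        as.numeric(x), as.numeric(z))
}

# MATLAB/scipy-style filtfilt: odd extension of 3*(order) samples at both
# ends, steady-state initial conditions scaled to the first/last extended
# sample, forward then backward pass, extension trimmed.
zeroPhaseFilter <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  padlen <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= padlen)
    stop("signal too short for stable zero-phase padding (need > ",
         padlen, " samples)")
  pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen, by = -1L)]
  xe <- c(pre, x, post)
  zi <- lfilterZi(b, a)
  y <- dfilt(b, a, xe, zi * xe[1L])
  y <- rev(dfilt(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

# Low-pass / band-pass Butterworth coefficients for a given sampling rate.
butterDesign <- function(order, cutoffHz, rateHz, type = c("low", "pass")) {
  type <- match.arg(type)
  w <- cutoffHz / (rateHz / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("cutoff must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(order, w, type = if (type == "low") "low" else "pass")
  list(b = bf$b, a = bf$a)
}

# Analytic magnitude of the designed digital filter at frequencies f (Hz).
butterMagnitude <- function(coef, f, rateHz) {
  w <- 2 * pi * f / rateHz
  num <- vapply(w, function(wk) sum(coef$b * exp(-1i * wk * (seq_along(coef$b) - 1L))),
                complex(1L))
  den <- vapply(w, function(wk) sum(coef$a * exp(-1i * wk * (seq_along(coef$a) - 1L))),
                complex(1L))
  Mod(num / den)
}

# Welch PSD: Hann-windowed overlapping segments, per-segment detrending,
# averaged modified periodograms. Returns one-sided frequencies (excluding
# DC) and density values. With segmentS >= the record length this degrades
# gracefully to a single windowed periodogram. Per-segment linear detrending
# (the default) suppresses spectral leakage of slow residual trends, which
# on 20 s records would otherwise bleed past 0.1 Hz.
welchPsd <- function(x, rate, segmentS = 10, overlap = 0.5,
                     window = c("hann", "none"),
                     detrend = c("linear", "mean")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  n <- length(x)
  seg <- min(n, max(32L, round(segmentS * rate)))
  step <- max(1L, floor(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  win <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(seg) - 1L) / (seg - 1L))
  } else rep(1, seg)
  U <- sum(win^2)
  idx <- seq_len(seg) - (seg + 1) / 2          # centered time index
  sxx <- sum(idx^2)
  nfreq <- seg %/% 2L
  acc <- numeric(nfreq)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]
    xs <- xs - mean(xs)
    if (detrend == "linear") xs <- xs - idx * sum(idx * xs) / sxx
    xs <- xs * win
    X <- stats::fft(xs)
    p <- Mod(X[2L:(nfreq + 1L)])^2 / (U * rate)
    # one-sided: double everything except Nyquist (when seg even)
    dbl <- rep(2, nfreq)
    if (seg %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (1:nfreq) * rate / seg, psd = acc / length(starts))
}

# Plain (single-segment, unwindowed, mean-detrended) periodogram via the
# same code path.
periodogramPsd <- function(x, rate) {
  welchPsd(x, rate, segmentS = length(x) / rate + 1, overlap = 0,
           window = "none", detrend = "mean")
}
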