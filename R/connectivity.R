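#' The four sensorimotor rhythm bands
#'
#' Fixed band set used for feature extraction: mu (8-12 Hz) and three beta
#' sub-bands, low (12-15), mid (15-20) and high (18-40); the mid/high overlap
#' is intentional and kept as defined.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz` in fixed order.
#' @export
rhythm_bands <- function() {
  data.frame(name = c("mu", "beta_l", "beta_m", "beta_h"),
             low_hz = c(8, 12, 15, 18),
             high_hz = c(12, 15, 20, 40))
}

#' Zero-phase band-pass filtering of a trial set
#'
#' @param trials a [trialset()].
#' @param band numeric length-2 `(low_hz, high_hz)`; must lie below Nyquist.
#' @param order Butterworth order (default 5).
#' @return The band-passed `trialset`.
#' @export
bandpass <- function(trials, band, order = 5) {
  stopifnot(inherits(trials, "trialset"), length(band) == 2, band[1] < band[2])
  if (band[2] >= trials$fs / 2) stop("band upper edge must be below Nyquist")
  b <- signal::butter(order, band / (trials$fs / 2), type = "pass")
  out <- trials$data
  for (t in seq_len(n_trials(trials)))
    for (c in seq_len(n_channels(trials)))
      out[t, c, ] <- signal::filtfilt(b, out[t, c, ])
  with_data(trials, out)
}

#' Crop trials to an analysis window
#'
#' Keeps samples in the half-open interval `[start_s, end_s)` relative to the
#' epoch's own time axis (`trials$window[1]` = first sample).
#'
#' @param trials a [trialset()].
#' @param start_s,end_s window bounds in seconds.
#' @return The cropped `trialset`.
#' @export
crop_window <- function(trials, start_s, end_s) {
  stopifnot(inherits(trials, "trialset"))
  t0 <- trials$window[1]
  i0 <- round((start_s - t0) * trials$fs) + 1
  i1 <- round((end_s - t0) * trials$fs)
  if (i0 < 1 || i1 > n_samples(trials)) stop("window outside trial extent")
  if (i1 < i0) stop("empty analysis window")
  trials$data <- trials$data[, , i0:i1, drop = FALSE]
  if (!is.null(trials$refs)) trials$refs <- trials$refs[, , i0:i1, drop = FALSE]
  trials$window <- c(start_s, end_s)
  trials
}

zero_var_warn <- function() warning("zero-variance series; correlation set to 0")

#' Pairwise functional-connectivity estimators
#'
#' Five scalar couplings between two single-channel time series over a trial
#' window: `fc_pearson` (sample Pearson correlation), `fc_motifs` (fraction of
#' coinciding ordinal patterns), `fc_gaussian` (time-averaged Gaussian kernel
#' of the sample-wise difference), `fc_coherence` (Welch-estimated spectral
#' coherence averaged over a frequency band), and `fc_plv` (phase-locking
#' value via the analytic signal).
#'
#' @param x,xp numeric vectors of equal length.
#' @return A scalar; coherence, PLV, Gaussian and motif values lie in `[0, 1]`,
#'   Pearson in `[-1, 1]`.
#' @export
fc_pearson <- function(x, xp) {
  stopifnot(length(x) == length(xp), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(xp) == 0) { zero_var_warn(); return(0) }
  stats::cor(x, xp)
}

# Ordinal pattern codes of degree 3: rank order of (x[t], x[t+lag], x[t+2 lag]),
# ties broken by earlier index. Returns integers in 1..6.
ordinal_patterns <- function(x, degree = 3, lag = 1) {
  n <- length(x) - (degree - 1) * lag
  m <- sapply(seq_len(degree) - 1, function(k) x[k * lag + seq_len(n)])
  codes <- integer(n)
  fact <- factorial(degree)
  for (i in seq_len(n)) {
    r <- rank(m[i, ], ties.method = "first")
    # Lehmer-style code of the permutation
    code <- 0L
    for (j in seq_len(degree - 1))
      code <- code + (sum(r[(j + 1):degree] < r[j])) * factorial(degree - j)
    codes[i] <- code + 1L
  }
  codes
}

#' @rdname fc_pearson
#' @param degree motif length in samples (default 3, giving 6 patterns).
#' @param lag sample lag between motif elements (default 1).
#' @export
fc_motifs <- function(x, xp, degree = 3, lag = 1) {
  stopifnot(length(x) == length(xp), length(x) >= degree * lag)
  mean(ordinal_patterns(x, degree, lag) == ordinal_patterns(xp, degree, lag))
}

#' @rdname fc_pearson
#' @param sigma Gaussian kernel bandwidth (> 0), same units as the signals.
#' @export
fc_gaussian <- function(x, xp, sigma) {
  stopifnot(length(x) == length(xp))
  if (sigma <= 0) stop("sigma must be positive")
  mean(exp(-(x - xp)^2 / (2 * sigma^2)))
}

# Welch auto-/cross-spectra: Hann-windowed segments with 50% overlap.
# Returns list(freq, sxy, sxx, syy) averaged over segments.
welch_cross <- function(x, xp, fs, seg_len) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  sxx <- syy <- numeric(seg_len)
  sxy <- complex(seg_len)
  for (s in starts) {
    idx <- s + seq_len(seg_len) - 1
    fx <- stats::fft(w * (x[idx] - mean(x[idx])))
    fy <- stats::fft(w * (xp[idx] - mean(xp[idx])))
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  k <- length(starts)
  half <- seq_len(floor(seg_len / 2) + 1)
  list(freq = (half - 1) * fs / seg_len,
       sxy = sxy[half] / k, sxx = sxx[half] / k, syy = syy[half] / k)
}

#' @rdname fc_pearson
#' @param fs sampling rate in Hz (coherence only).
#' @param band frequency band `(low, high)` over which coherence is averaged;
#'   `NULL` averages over the whole spectrum.
#' @param seg_len Welch segment length; default `min(256, floor(n/4))`.
#' @export
fc_coherence <- function(x, xp, fs = 1, band = NULL, seg_len = NULL) {
  n <- length(x)
  stopifnot(n == length(xp), n >= 64)
  if (is.null(seg_len)) seg_len <- max(8, min(256, floor(n / 4)))
  wc <- welch_cross(x, xp, fs, seg_len)
  sel <- if (is.null(band)) wc$freq > 0 else wc$freq >= band[1] & wc$freq <= band[2]
  if (!any(sel)) sel <- rep(TRUE, length(wc$freq))
  denom <- sqrt(wc$sxx[sel] * wc$syy[sel])
  if (all(denom == 0)) { warning("zero power in band; coherence set to 0"); return(0) }
  ok <- denom > 0
  mean(Mod(wc$sxy[sel][ok]) / denom[ok])
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  stats::fft(f * h, inverse = TRUE) / n
}

#' @rdname fc_pearson
#' @export
fc_plv <- function(x, xp) {
  stopifnot(length(x) == length(xp))
  ax <- analytic_signal(x); ay <- analytic_signal(xp)
  amp <- Mod(ax) * Mod(ay)
  ok <- amp > 0
  if (!all(ok)) warning("zero instantaneous amplitude; samples skipped")
  if (!any(ok)) return(0)
  ph <- Arg(ax[ok]) - Arg(ay[ok])
  Mod(mean(exp(1i * ph)))
}

# Full pairwise FC matrix (upper triangle used) for one trial's band-passed
# data X (C x T). Vectorized paths where the estimator allows it.
fc_matrix <- function(X, measure, fs, band, sigma = NULL) {
  C <- nrow(X)
  switch(measure,
    pearson = {
      sds <- apply(X, 1, stats::sd)
      M <- suppressWarnings(stats::cor(t(X)))
      M[sds == 0, ] <- 0; M[, sds == 0] <- 0
      M
    },
    plv = {
      Z <- t(apply(X, 1, function(v) {
        a <- analytic_signal(v); a / ifelse(Mod(a) > 0, Mod(a), 1)
      }))
      Mod(tcrossprod(Z, Conj(Z))) / ncol(X)
    },
    gfc = {
      M <- matrix(1, C, C)
      for (i in seq_len(C - 1)) for (j in (i + 1):C)
        M[i, j] <- M[j, i] <- fc_gaussian(X[i, ], X[j, ], sigma)
      M
    },
    motifs = {
      P <- t(apply(X, 1, ordinal_patterns))
      M <- matrix(1, C, C)
      for (i in seq_len(C - 1)) for (j in (i + 1):C)
        M[i, j] <- M[j, i] <- mean(P[i, ] == P[j, ])
      M
    },
    coherence = {
      M <- matrix(1, C, C)
      for (i in seq_len(C - 1)) for (j in (i + 1):C)
        M[i, j] <- M[j, i] <- fc_coherence(X[i, ], X[j, ], fs, band)
      M
    },
    stop("unknown FC measure: ", measure))
}

#' Upper-triangular pair ordering of the feature vector
#'
#' @param n_channels number of channels C.
#' @param bands band table as from [rhythm_bands()].
#' @return A data frame `(band, i, j)` with `i < j` in row-major
#'   upper-triangular order, bands concatenated in their fixed order; one row
#'   per feature, `4 * C * (C - 1) / 2` rows for the default bands.
#' @export
fc_pair_index <- function(n_channels, bands = rhythm_bands()) {
  ut <- which(upper.tri(matrix(0, n_channels, n_channels)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]  # row-major i<j
  do.call(rbind, lapply(bands$name, function(b)
    data.frame(band = b, i = ut[, 1], j = ut[, 2])))
}

#' Build the per-trial functional-connectivity feature matrix
#'
#' For every trial and every rhythm band: crop to the analysis window,
#' band-pass filter, estimate the pairwise FC matrix, and keep the vectorized
#' upper triangle (row-major, i < j). Band blocks are concatenated in the
#' fixed [rhythm_bands()] order, giving `4 * C * (C - 1) / 2` features per
#' trial. For the Gaussian kernel measure the bandwidth is set per trial and
#' band to the median absolute sample-wise difference pooled over all channel
#' pairs (the median heuristic); `sigma_mode = "pair"` switches to a per-pair
#' median.
#'
#' @param trials a [trialset()].
#' @param measure one of `"pearson"`, `"motifs"`, `"gfc"`, `"coherence"`,
#'   `"plv"`.
#' @param window analysis window `(start_s, end_s)` or `NULL` for the full
#'   epoch.
#' @param bands band table (default [rhythm_bands()]).
#' @param sigma_mode `"pooled"` (default) or `"pair"` Gaussian bandwidth.
#' @return trials x features numeric matrix with attribute `pair_index`.
#' @export
build_features <- function(trials, measure = "gfc", window = NULL,
                           bands = rhythm_bands(), sigma_mode = "pooled") {
  measure <- match.arg(measure, c("pearson", "motifs", "gfc", "coherence", "plv"))
  if (!is.null(window)) trials <- crop_window(trials, window[1], window[2])
  C <- n_channels(trials)
  pidx <- fc_pair_index(C, bands)
  ut <- upper.tri(matrix(0, C, C))
  feats <- matrix(0, n_trials(trials), nrow(pidx))
  col0 <- 0
  for (b in seq_len(nrow(bands))) {
    band <- c(bands$low_hz[b], bands$high_hz[b])
    bp <- bandpass(trials, band)
    pr <- which(ut, arr.ind = TRUE)
    for (t in seq_len(n_trials(trials))) {
      X <- bp$data[t, , ]
      M <- if (measure == "gfc" && sigma_mode == "pair") {
        Mm <- matrix(1, C, C)
        for (i in seq_len(C - 1)) for (j in (i + 1):C) {
          s_ij <- stats::median(abs(X[i, ] - X[j, ]))
          if (s_ij == 0) s_ij <- .Machine$double.eps
          Mm[i, j] <- Mm[j, i] <- fc_gaussian(X[i, ], X[j, ], s_ij)
        }
        Mm
      } else {
        sigma <- NULL
        if (measure == "gfc") {
          sigma <- stats::median(abs(X[pr[, 1], ] - X[pr[, 2], ]))
          if (sigma == 0) stop("degenerate Gaussian bandwidth (all pairs identical)")
        }
        fc_matrix(X, measure, trials$fs, band, sigma)
      }
      Mt <- t(M)                     # row-major upper triangle = t(M)[lower]
      feats[t, col0 + seq_len(sum(ut))] <- Mt[lower.tri(Mt)]
    }
    col0 <- col0 + sum(ut)
  }
  attr(feats, "pair_index") <- pidx
  attr(feats, "measure") <- measure
  feats
}
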