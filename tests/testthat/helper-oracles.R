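# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: band power by raw periodogram, Legendre values by
# pracma's associated-Legendre routine, RMS error by direct arithmetic.

# mean periodogram power of x in [lo, hi] Hz
band_power <- function(x, fs, lo, hi) {
  p <- Mod(stats::fft(x))^2 / length(x)
  f <- (seq_along(x) - 1) * fs / length(x)
  mean(p[f >= lo & f <= hi])
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# term-by-term spline kernel using pracma's Legendre recurrence (independent
# of the package's implementation)
kernel_oracle <- function(cos_angle, order_o, expo) {
  sum(vapply(seq_len(order_o), function(n)
    (2 * n + 1) * pracma::legendre(n, cos_angle)[1] / (n * (n + 1))^expo,
    numeric(1))) / (4 * pi)
}

# count of strong Pearson links between channel `ch` and all others, averaged
# over trials (computed directly from the tensor, not via build_features)
strong_links <- function(ts, ch, thr = 0.5) {
  n <- 0
  for (t in seq_len(dim(ts$data)[1])) {
    r <- stats::cor(t(ts$data[t, , ]))
    n <- n + sum(abs(r[ch, -ch]) > thr)
  }
  n / dim(ts$data)[1]
}

# great-circle angles from electrode `idx` to every electrode
great_circle_rows <- function(pos, idx) {
  d <- drop(pos %*% pos[idx, ])
  acos(pmin(1, pmax(-1, d)))
}

# a small trialset of pure Gaussian noise
noise_trials <- function(n_tr = 4, C = 8, Tn = 500, fs = 250, seed = 1) {
  set.seed(seed)
  trialset(array(stats::rnorm(n_tr * C * Tn), c(n_tr, C, Tn)), fs,
           positions = synthetic_montage(C),
           labels = factor(rep(0:1, length.out = n_tr)))
}
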