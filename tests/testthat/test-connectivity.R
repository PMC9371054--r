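test_that("band-pass and crop behave on known signals", {
  fs <- 250
  tt <- seq(1 / fs, 4, by = 1 / fs)
  ts <- trialset(array(rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 30 * tt)),
                       c(1, 2, length(tt))), fs)
  mu <- bandpass(ts, c(8, 12))
  expect_gt(rmse(mu$data[1, 1, ], 0), 0.90 * rmse(sin(2 * pi * 10 * tt), 0))
  expect_lt(rmse(mu$data[1, 2, ], 0), 0.05 * rmse(sin(2 * pi * 30 * tt), 0))
  zero <- bandpass(trialset(array(0, c(1, 1, 1000)), fs), c(8, 12))
  expect_equal(max(abs(zero$data)), 0)
  expect_error(bandpass(ts, c(8, 130)), "Nyquist")

  cw <- crop_window(ts, 0.5, 3.5)
  expect_equal(dim(cw$data)[3], 750)
  ts512 <- trialset(array(0, c(1, 1, 512 * 3)), 512)
  expect_equal(dim(crop_window(ts512, 0.5, 2.5)$data)[3], 1024)
  expect_identical(dim(crop_window(ts, 0, 4)$data), dim(ts$data))
  expect_error(crop_window(ts, 3, 5), "extent")
})

test_that("FC estimators satisfy their identities and closed forms", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  # hand-computable small-vector values
  expect_equal(fc_pearson(x, y),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_equal(fc_pearson(x, x), 1)
  expect_equal(fc_pearson(x, -x), -1)
  expect_warning(z <- fc_pearson(rep(1, 8), x), "zero-variance")
  expect_equal(z, 0)

  expect_equal(fc_motifs(x, x), 1)
  expect_equal(fc_motifs(1:10, 10:1), 0)

  expect_equal(fc_gaussian(x, x, 1), 1)
  expect_equal(fc_gaussian(rep(0, 8), rep(2, 8), sigma = 2), exp(-1 / 2))
  expect_equal(fc_gaussian(x, y, 1), mean(exp(-(x - y)^2 / 2)), tolerance = 1e-12)
  expect_error(fc_gaussian(x, y, 0), "positive")

  n <- 2048
  w <- stats::rnorm(n)
  expect_equal(fc_coherence(w, w), 1, tolerance = 1e-10)
  # a pure delay within a single segment keeps coherence magnitude at 1
  expect_equal(fc_coherence(w[1:1000], c(w[5:1000], stats::rnorm(4)),
                            seg_len = 1000), 1, tolerance = 1e-6)

  tt <- seq(0, 8, by = 1 / 250)
  s1 <- sin(2 * pi * 10 * tt)
  expect_equal(fc_plv(s1, s1), 1, tolerance = 1e-12)
  expect_equal(fc_plv(s1, sin(2 * pi * 10 * tt + pi / 3)), 1, tolerance = 1e-3)
})

test_that("independent-signal nulls land at their analytic levels", {
  set.seed(31)
  a <- stats::runif(1e5); b <- stats::runif(1e5)
  expect_equal(fc_motifs(a, b), 1 / 6, tolerance = 0.02)

  w1 <- stats::rnorm(1e4); w2 <- stats::rnorm(1e4)
  expect_lt(fc_coherence(w1, w2, seg_len = 1250), 0.45)

  bp <- function(seed) {
    set.seed(seed)
    bandpass(trialset(array(stats::rnorm(1e4), c(1, 1, 1e4)), 250),
             c(8, 12))$data[1, 1, ]
  }
  expect_lt(fc_plv(bp(1), bp(2)), 0.1)
})

test_that("feature vectors have the printed dimension and clean pair order", {
  for (C in c(16, 22)) {
    pidx <- fc_pair_index(C)
    expect_equal(nrow(pidx), 4 * C * (C - 1) / 2)
    expect_true(all(pidx$i < pidx$j))
    expect_false(any(duplicated(pidx)))
  }
  g <- generate_mi_trials(1, 4, 16, 250, 1, 10, seed = 2)
  f <- build_features(g$trials, "pearson")
  expect_equal(dim(f), c(4, 480))
  expect_error(build_features(g$trials, "nope"), "arg")
})

test_that("FC values are symmetric, bounded, and permutation-equivariant", {
  set.seed(41)
  x <- stats::rnorm(600); y <- stats::rnorm(600)
  for (f in list(fc_motifs, function(a, b) fc_gaussian(a, b, 1), fc_plv,
                 function(a, b) fc_coherence(a, b, seg_len = 150)))
    expect_equal(f(x, y), f(y, x), tolerance = 1e-12)
  expect_equal(fc_pearson(x, y), fc_pearson(y, x), tolerance = 1e-12)

  g <- generate_mi_trials(1, 4, 8, 250, 1, 10, seed = 3)
  for (m in c("pearson", "motifs", "gfc", "coherence", "plv")) {
    f <- build_features(g$trials, m)
    if (m == "pearson") {
      expect_true(all(f >= -1 & f <= 1))
    } else {
      expect_true(all(f >= 0 & f <= 1 + 1e-9))
    }
  }

  # permuting channels permutes pairs: feature multiset is unchanged
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  gp <- g$trials
  gp$data <- gp$data[, perm, ]
  gp$positions <- gp$positions[perm, ]
  gp$channel_names <- gp$channel_names[perm]
  f0 <- build_features(g$trials, "pearson")
  fp <- build_features(gp, "pearson")
  expect_equal(sort(round(f0[2, ], 10)), sort(round(fp[2, ], 10)))
})

test_that("Laplacian filtering weakens distant FC on volume-conducted data", {
  g <- generate_mi_trials(1, 10, 16, 250, 2, 10, seed = 8)
  sl <- surface_laplacian(g$trials)
  cz <- which.max(g$trials$positions[, 3])
  far <- which(great_circle_rows(g$trials$positions, cz) > 1.0)
  f_raw <- build_features(g$trials, "pearson")
  f_sl <- build_features(sl, "pearson")
  pidx <- attr(f_raw, "pair_index")
  sel <- (pidx$i == cz & pidx$j %in% far) | (pidx$j == cz & pidx$i %in% far)
  expect_lt(mean(abs(f_sl[, sel])), mean(abs(f_raw[, sel])))
})
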