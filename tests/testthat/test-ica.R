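test_that("high-pass keeps the passband and kills drifts", {
  fs <- 250
  tt <- seq(0, 4, by = 1 / fs)[-1]
  slow <- sin(2 * pi * 0.1 * tt)
  fast <- sin(2 * pi * 10 * tt)
  ts <- trialset(array(rbind(slow, fast), c(1, 2, length(tt))), fs)
  out <- highpass_for_ica(ts)
  expect_lt(rmse(out$data[1, 1, ], 0), 0.05 * rmse(slow, 0))
  expect_gt(rmse(out$data[1, 2, ], 0), 0.95 * rmse(fast, 0))
  zero <- trialset(array(0, c(1, 1, 1000)), fs)
  expect_equal(max(abs(highpass_for_ica(zero)$data)), 0)
  expect_error(highpass_for_ica(trialset(array(0, c(1, 1, 20)), fs)), "warm-up")
})

test_that("FastICA recovers independent sources up to sign and permutation", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    S <- matrix(stats::runif(3 * 6000, -1, 1), 3)
    A <- matrix(stats::rnorm(9), 3)
    tr <- trialset(array(A %*% S, c(1, 3, 6000)), 250)
    ica <- suppressWarnings(fit_fastica(tr, seed = seed))
    cc <- abs(stats::cor(t(ica$sources_S), t(S)))
    expect_gt(min(apply(cc, 2, max)), 0.99)
    # reconstruction identity and unit-variance sources
    rec <- remove_and_reconstruct(tr, ica, rep(TRUE, 3))
    expect_lt(max(abs(rec$data - tr$data)) / max(abs(tr$data)), 1e-6)
    expect_equal(apply(ica$sources_S, 1, stats::var), rep(1, 3),
                 tolerance = 1e-3)
  }
})

test_that("component scoring matches Pearson identities", {
  g <- generate_mi_trials(1, 8, 8, 250, 1, 10, seed = 5)
  hp <- highpass_for_ica(g$trials)
  ica <- suppressWarnings(fit_fastica(hp, seed = 1))
  # a reference equal to a component scores 1, scaling by -5 changes nothing
  refs <- rbind(ica$sources_S[2, ], -5 * ica$sources_S[2, ])
  sc <- score_components(ica, refs)
  expect_equal(sc[2, 1], 1, tolerance = 1e-12)
  expect_equal(sc[2, 2], 1, tolerance = 1e-12)
  # independent white noise scores near zero
  set.seed(9)
  noise_ref <- matrix(stats::rnorm(ncol(ica$sources_S)), 1)
  sc2 <- score_components(ica, noise_ref)
  expect_lt(max(sc2), 0.1)  # per-trial means over short segments
})

test_that("3-sigma threshold isolates outliers and handles degeneracy", {
  expect_warning(m <- threshold_3sigma(rep(0.3, 10)), "zero variance")
  expect_true(all(m$keep))
  expect_equal(m$gamma, Inf)

  s <- c(rep(0.05, 63), 0.9)
  m2 <- threshold_3sigma(s)
  expect_equal(which(!m2$keep), 64L)

  set.seed(21)
  p <- stats::pnorm(3, lower.tail = FALSE)
  frac <- mean(!threshold_3sigma(stats::rnorm(1e4))$keep)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("reconstruction is a projection and refuses to drop everything", {
  g <- generate_mi_trials(1, 8, 8, 250, 1, 10, seed = 6)
  hp <- highpass_for_ica(g$trials)
  ica <- suppressWarnings(fit_fastica(hp, seed = 2))
  keep <- c(TRUE, FALSE, rep(TRUE, 6))
  once <- remove_and_reconstruct(hp, ica, keep)
  twice <- remove_and_reconstruct(once, ica, keep)
  expect_lt(max(abs(twice$data - once$data)), 1e-8)
  expect_error(remove_and_reconstruct(hp, ica, rep(FALSE, 8)), "all-zero")
  expect_error(remove_and_reconstruct(hp, ica, keep[1:3]), "length")
})

test_that("two-pass cleaning reduces blink correlation at frontal channels", {
  for (seed in 1:2) {
    g <- inject_eog(generate_mi_trials(1, 30, 16, 250, 2, 10, seed = seed),
                    blink_rate_hz = 1, amplitude_uv = 150, seed = seed)
    fi <- frontal_indices(g$trials$positions)
    cl <- suppressWarnings(ica_clean(g$trials, ref_mode = "eog", seed = seed))
    ref <- as.vector(t(g$truth$eog_reference))
    hp <- suppressWarnings(highpass_for_ica(g$trials))
    before <- abs(stats::cor(ref, as.vector(t(hp$data[, fi[1], ]))))
    after <- abs(stats::cor(ref, as.vector(t(cl$data[, fi[1], ]))))
    expect_lt(after, before)
  }
})
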