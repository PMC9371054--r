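test_that("scenario variants are aligned and compositional", {
  g <- inject_eog(generate_mi_trials(1, 20, 12, 250, 2, 10, seed = 1),
                  1, 150, seed = 1)
  v <- suppressWarnings(scenario_variants(g$trials, ref_mode = "eog",
                                          ica_params = list(seed = 1, passes = 1)))
  expect_identical(v$eta0$data, g$trials$data)
  for (nm in names(v)) {
    expect_identical(dim(v[[nm]]$data), dim(g$trials$data))
    expect_identical(v[[nm]]$labels, g$trials$labels)
  }
  # eta3 is the Laplacian of the ICA-cleaned data, in that order
  sm <- build_spline_matrices(g$trials$positions)
  expect_equal(v$eta3$data, surface_laplacian(v$eta1, sm)$data, tolerance = 1e-12)
})

test_that("selection is the argmax with smallest-eta tie-break", {
  # equal accuracies everywhere must give eta = 0
  fake <- list(acc_by_eta = c(eta0 = 70, eta1 = 70, eta2 = 70, eta3 = 70))
  sel <- as.integer(sub("eta", "", names(fake$acc_by_eta)[which.max(fake$acc_by_eta)]))
  expect_equal(sel, 0L)

  g <- generate_mi_trials(1, 24, 8, 250, 1, 10, seed = 2)
  sc <- suppressWarnings(select_eta(g$trials, measure = "pearson", seed = 2))
  expect_true(sc$selected_eta %in% 0:3)
  expect_equal(max(sc$acc_by_eta), sc$acc_by_eta[[paste0("eta", sc$selected_eta)]])
  expect_error(select_eta(g$trials[1:10], measure = "pearson"), "at least 20")
})

test_that("the fitted sdar object dominates its forced baselines on validation", {
  g <- inject_eog(generate_mi_trials(1, 30, 10, 250, 2, 5, seed = 3),
                  1, 200, seed = 3)
  fit <- suppressWarnings(sdar(g$trials, measure = "pearson", seed = 3,
                               ref_mode = "eog"))
  expect_gte(max(fit$score$acc_by_eta), fit$score$acc_by_eta[["eta0"]])
  expect_gte(max(fit$score$acc_by_eta), fit$score$acc_by_eta[["eta3"]])
  s <- summary(fit)
  expect_equal(nrow(s$table), 3)
  # forced runs reproduce the standalone scenario outputs
  forced <- suppressWarnings(sdar(g$trials, measure = "pearson", seed = 3,
                                  ref_mode = "eog", force_eta = 0L))
  expect_identical(forced$sdar$acc, forced$raw$acc)
})

test_that("sdar is deterministic and selection never sees the test set", {
  g <- generate_mi_trials(1, 24, 8, 250, 1, 10, seed = 4)
  f1 <- suppressWarnings(sdar(g$trials, measure = "pearson", seed = 4))
  f2 <- suppressWarnings(sdar(g$trials, measure = "pearson", seed = 4))
  expect_identical(f1$score$acc_by_eta, f2$score$acc_by_eta)
  expect_identical(f1$sdar$acc, f2$sdar$acc)

  # poison the held-out trials: the selection must not change
  poisoned <- g$trials
  poisoned$data[f1$test_idx, , ] <- stats::rnorm(length(poisoned$data[f1$test_idx, , ]))
  f3 <- suppressWarnings(sdar(poisoned, measure = "pearson", seed = 4,
                              test_idx = f1$test_idx))
  f1b <- suppressWarnings(sdar(g$trials, measure = "pearson", seed = 4,
                               test_idx = f1$test_idx))
  expect_identical(f3$score$selected_eta, f1b$score$selected_eta)
  expect_identical(f3$score$acc_by_eta, f1b$score$acc_by_eta)
})
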