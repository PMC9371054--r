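#' The four preprocessing scenarios
#'
#' Computes the preprocessing variant of a subject's trials for every value of
#' the selector coefficient eta: 0 = raw, 1 = ICA-cleaned, 2 =
#' surface-Laplacian filtered, 3 = ICA followed by the Laplacian (the
#' sequential order used throughout). All four variants share trial/label
#' alignment; the ICA variant is computed once and reused for eta = 3.
#'
#' @param trials a [trialset()] with electrode positions.
#' @param ref_mode artifact reference mode for the ICA stage (`"frontal"` or
#'   `"eog"`, see [ica_clean()]).
#' @param sl_params list of surface-Laplacian parameters `(order_o, rho,
#'   lambda_reg)`.
#' @param ica_params list of ICA parameters `(seed, passes)`.
#' @param fit_idx trial indices the ICA stage may learn from (default all);
#'   see [ica_clean()].
#' @return Named list `eta0` ... `eta3` of `trialset` objects.
#' @export
scenario_variants <- function(trials, ref_mode = "frontal",
                              sl_params = list(order_o = 10, rho = 4,
                                               lambda_reg = 1e-5),
                              ica_params = list(seed = 0, passes = 2),
                              fit_idx = NULL) {
  sm <- build_spline_matrices(trials$positions, sl_params$order_o,
                              sl_params$rho, sl_params$lambda_reg)
  cleaned <- ica_clean(trials, ref_mode = ref_mode, seed = ica_params$seed,
                       passes = ica_params$passes, fit_idx = fit_idx)
  list(eta0 = trials,
       eta1 = cleaned,
       eta2 = surface_laplacian(trials, sm),
       eta3 = surface_laplacian(cleaned, sm))
}

#' Select the preprocessing scenario by validation accuracy
#'
#' Estimates a cross-validated classification accuracy for each available
#' preprocessing scenario and picks the argmax, breaking ties toward the
#' smallest eta (least processing). Only the supplied trials — normally a
#' subject's training portion — are ever seen, so the selection cannot leak
#' held-out test information.
#'
#' @param variants named list from [scenario_variants()] (or a `trialset`, in
#'   which case variants are computed with defaults).
#' @param measure FC measure used for the features (see [build_features()]).
#' @param window analysis window passed to [build_features()].
#' @param seed fold seed.
#' @param k_select folds for the selection CV (default 5).
#' @return An object of class `scenario_score`: `acc_by_eta` (percent, named
#'   `eta0..eta3`), `selected_eta` (integer 0-3), `measure`.
#' @export
select_eta <- function(variants, measure = "gfc", window = NULL, seed = 0,
                       k_select = 5) {
  if (inherits(variants, "trialset")) {
    if (n_trials(variants) < 20)
      stop("need at least 20 trials to select a scenario")
    variants <- scenario_variants(variants)
  }
  labels <- variants[[1]]$labels
  if (length(labels) < 20) stop("need at least 20 trials to select a scenario")
  acc <- vapply(variants, function(v) {
    f <- build_features(v, measure, window = window)
    evaluate(f, labels, scheme = "kfold10", seed = seed, k = k_select)$acc
  }, numeric(1))
  sel <- as.integer(sub("eta", "", names(acc)[which.max(acc)]))
  structure(list(acc_by_eta = acc, selected_eta = sel, measure = measure,
                 seed = seed),
            class = "scenario_score")
}

#' @export
print.scenario_score <- function(x, ...) {
  nm <- c("raw", "ica", "laplacian", "ica_then_laplacian")
  cat("<scenario_score> validation accuracy by scenario:\n")
  for (i in seq_along(x$acc_by_eta))
    cat(sprintf("  eta=%d (%-18s) %5.1f%%%s\n", i - 1, nm[i], x$acc_by_eta[i],
                if (i - 1 == x$selected_eta) "  <- selected" else ""))
  invisible(x)
}

#' Subject-dependent artifact removal (SD-AR)
#'
#' Fits the full per-subject pipeline: the four preprocessing scenarios are
#' computed, a validation accuracy is estimated for each by stratified
#' cross-validation on the training portion only, the best scenario is
#' selected (ties to the least processing), and the selected variant is
#' evaluated on the held-out test trials. The two fixed baselines are
#' evaluated the same way: `raw` forces eta = 0 and `ind_ar` (subject-
#' independent artifact removal) forces eta = 3.
#'
#' @param trials a [trialset()] with labels and positions.
#' @param measure FC measure for feature extraction (default `"gfc"`).
#' @param window analysis window `(start_s, end_s)` or `NULL`.
#' @param scheme final-evaluation scheme: `"fixed_test"` (default; train on
#'   the training portion, report on the held-out 20%), `"kfold10"` or
#'   `"split2080x10"` (applied to the full trial set, selection still made on
#'   the training portion only).
#' @param seed integer seed driving the holdout split, selection folds and the
#'   ICA fit.
#' @param test_idx optional explicit held-out trial indices; otherwise a
#'   stratified 20% holdout is drawn from `seed`.
#' @param force_eta optionally force the selector to a fixed scenario 0-3.
#' @param ref_mode,sl_params,ica_params passed to [scenario_variants()];
#'   `ica_params$seed` defaults to `seed`.
#' @param k_select folds for the selection CV.
#' @return An object of class `sdar`: the `scenario_score`, final
#'   `eval_result`s for `sdar`, `raw` and `ind_ar`, and the split indices.
#' @export
sdar <- function(trials, measure = "gfc", window = NULL,
                 scheme = c("fixed_test", "kfold10", "split2080x10"),
                 seed = 0, test_idx = NULL, force_eta = NULL,
                 ref_mode = "frontal",
                 sl_params = list(order_o = 10, rho = 4, lambda_reg = 1e-5),
                 ica_params = list(seed = seed, passes = 2),
                 k_select = 5) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(trials, "trialset"), !is.null(trials$labels))
  labels <- trials$labels
  if (is.null(test_idx)) {
    set.seed(seed + 101L)
    test_idx <- sort(unlist(lapply(levels(labels), function(l) {
      idx <- which(labels == l)
      sample(idx, max(1, round(0.2 * length(idx))))
    })))
  }
  train_idx <- setdiff(seq_along(labels), test_idx)

  variants <- scenario_variants(trials, ref_mode, sl_params, ica_params,
                                fit_idx = train_idx)
  train_variants <- lapply(variants, function(v) v[train_idx])
  score <- select_eta(train_variants, measure, window, seed, k_select)
  if (!is.null(force_eta)) score$selected_eta <- as.integer(force_eta)

  eval_variant <- function(eta) {
    v <- variants[[paste0("eta", eta)]]
    f <- build_features(v, measure, window = window)
    if (scheme == "fixed_test") {
      evaluate(f[train_idx, , drop = FALSE], labels[train_idx],
               scheme = "fixed_test", seed = seed,
               test = list(x = f[test_idx, , drop = FALSE],
                           labels = labels[test_idx]))
    } else {
      evaluate(f, labels, scheme = scheme, seed = seed)
    }
  }
  res <- list(score = score,
              sdar = eval_variant(score$selected_eta),
              raw = eval_variant(0L),
              ind_ar = eval_variant(3L),
              measure = measure, scheme = scheme, seed = seed,
              train_idx = train_idx, test_idx = test_idx)
  class(res) <- "sdar"
  res
}

#' @export
print.sdar <- function(x, ...) {
  cat(sprintf("SD-AR fit (measure=%s, scheme=%s, seed=%d)\n",
              x$measure, x$scheme, x$seed))
  print(x$score)
  cat(sprintf("  test ACC: SD-AR %.1f%% | Raw %.1f%% | Ind-AR %.1f%%\n",
              x$sdar$acc, x$raw$acc, x$ind_ar$acc))
  invisible(x)
}

#' @export
summary.sdar <- function(object, ...) {
  out <- data.frame(
    scenario = c("sdar", "raw", "ind_ar"),
    selected_eta = c(object$score$selected_eta, 0L, 3L),
    acc = c(object$sdar$acc, object$raw$acc, object$ind_ar$acc),
    kappa = c(object$sdar$kappa, object$raw$kappa, object$ind_ar$kappa),
    auc = c(object$sdar$auc, object$raw$auc, object$ind_ar$auc))
  structure(list(table = out, score = object$score), class = "summary.sdar")
}

#' @export
print.summary.sdar <- function(x, ...) {
  print(x$score)
  print(x$table, row.names = FALSE)
  invisible(x)
}
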