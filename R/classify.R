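#' Linear discriminant analysis with a singular-value solver
#'
#' Gaussian LDA with a shared (pooled) covariance estimated from the
#' within-class centered data. The covariance is inverted through its singular
#' value decomposition with a small diagonal shrinkage
#' `alpha = shrink * tr(Sigma) / p`, so rank-deficient problems — duplicated
#' features, zero within-class variance, more features than samples, as FC
#' feature matrices routinely are — are handled without error (the Woodbury
#' form keeps the cost at O(n^2 p) for p >> n). Class scores are
#' `x' C_k + b_k` with `C_k = (Sigma + alpha I)^{-1} mu_k` and
#' `b_k = -mu_k' C_k / 2 + log pi_k`.
#'
#' @param x numeric matrix, samples x features.
#' @param labels factor (or coercible) with >= 2 classes, >= 2 samples each.
#' @param shrink relative diagonal shrinkage of the pooled covariance
#'   (default 1e-3).
#' @return An object of class `lda_model` with per-class coefficient vectors
#'   (`coefficients`, features x classes), intercepts, class means and levels.
#' @export
fit_lda <- function(x, labels, shrink = 1e-3) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  if (length(lv) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("need at least 2 samples per class")
  n <- nrow(x); K <- length(lv); p <- ncol(x)
  mu <- t(sapply(lv, function(l) colMeans(x[labels == l, , drop = FALSE])))
  prior <- as.numeric(table(labels)[lv]) / n
  xc <- x - mu[as.integer(factor(labels, levels = lv)), , drop = FALSE]
  sv <- svd(xc, nu = 0)
  ev <- sv$d^2 / max(1, n - K)                  # eigenvalues of pooled Sigma
  alpha <- shrink * sum(ev) / p
  if (alpha == 0) alpha <- shrink               # all-constant within classes
  # (Sigma + alpha I)^{-1} = V diag(1/(ev+alpha)) V' + (I - V V') / alpha
  V <- sv$v[, sv$d > 0, drop = FALSE]
  ev <- ev[sv$d > 0]
  Vm <- crossprod(V, t(mu))                     # r x K
  coefs <- (t(mu) - V %*% Vm) / alpha + V %*% (Vm / (ev + alpha))
  intercept <- -0.5 * colSums(t(mu) * coefs) + log(prior)
  structure(list(coefficients = coefs, intercept = intercept, means = mu,
                 prior = prior, levels = lv),
            class = "lda_model")
}

#' @rdname fit_lda
#' @param object an `lda_model`.
#' @param newdata samples x features matrix.
#' @param ... ignored.
#' @return `predict` returns a list with `class` (factor) and `scores`
#'   (samples x classes linear discriminant scores).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  s <- newdata %*% object$coefficients
  s <- sweep(s, 2, object$intercept, "+")
  colnames(s) <- object$levels
  cls <- factor(object$levels[max.col(s, ties.method = "first")],
                levels = object$levels)
  list(class = cls, scores = s)
}

#' @rdname fit_lda
#' @export
coef.lda_model <- function(object, ...) object$coefficients

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the
#' marginal-product expected agreement.
#'
#' @param confusion square non-negative matrix, rows = truth, columns =
#'   prediction.
#' @return kappa in `[-1, 1]`; 0 (with a warning) when expected agreement is 1.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) { warning("expected agreement is 1; kappa set to 0"); return(0) }
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Rank-based AUC equal to the normalized Mann-Whitney statistic (ties counted
#' half). Binary labels use a score vector for the second level; multiclass
#' uses a samples x classes score matrix and macro-averages one-vs-rest AUCs.
#'
#' @param scores numeric vector (binary) or matrix (multiclass, one column per
#'   class level).
#' @param labels factor (or coercible) of true classes.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  if (length(lv) < 2) stop("AUC undefined for a single class")
  binary_auc <- function(s, pos) {
    n1 <- sum(pos); n0 <- sum(!pos)
    r <- rank(s)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  }
  if (length(lv) == 2 && is.null(dim(scores)))
    return(binary_auc(scores, labels == lv[2]))
  scores <- as.matrix(scores)
  if (length(lv) == 2 && ncol(scores) >= 2)
    return(binary_auc(scores[, 2] - scores[, 1], labels == lv[2]))
  mean(vapply(seq_along(lv), function(k)
    binary_auc(scores[, k], labels == lv[k]), numeric(1)))
}

# Stratified fold assignment: per class, shuffled indices dealt round-robin,
# so every fold's class counts are within 1 of the global proportions.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (l in levels(as.factor(labels))) {
    idx <- sample(which(labels == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# z-score standardization fitted on the training rows only.
standardize_fit <- function(x) {
  m <- colMeans(x); s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  list(mean = m, sd = s)
}
standardize_apply <- function(x, st) sweep(sweep(x, 2, st$mean), 2, st$sd, "/")

#' Cross-validated classifier evaluation
#'
#' Trains the pseudoinverse LDA on standardized features (z-score fitted on the
#' training rows of each fold, preventing leakage) and reports accuracy,
#' Cohen's kappa and AUC. Three validation schemes: `"kfold10"` (stratified
#' k-fold), `"split2080x10"` (ten random stratified splits with 80% training /
#' 20% testing), and `"fixed_test"` (train on `x`/`labels`, report on the
#' supplied test set).
#'
#' @param x samples x features matrix.
#' @param labels factor of class labels.
#' @param scheme validation scheme (see above).
#' @param seed integer seed controlling fold/split assignment.
#' @param k number of folds for `"kfold10"` (default 10).
#' @param test list `(x, labels)` for `"fixed_test"`.
#' @return An object of class `eval_result`: pooled `acc` (percent), `kappa`
#'   and `auc` from the pooled out-of-fold predictions, the pooled `confusion`
#'   matrix, `per_fold` metrics, and their `mean_sd` summary.
#' @export
evaluate <- function(x, labels, scheme = c("kfold10", "split2080x10", "fixed_test"),
                     seed = 0, k = 10, test = NULL) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x); labels <- droplevels(as.factor(labels))
  lv <- levels(labels)
  splits <- switch(scheme,
    kfold10 = {
      fold <- stratified_folds(labels, k, seed)
      lapply(seq_len(k), function(f)
        list(train = which(fold != f), test = which(fold == f)))
    },
    split2080x10 = lapply(seq_len(10), function(i) {
      set.seed(seed + i)
      te <- unlist(lapply(lv, function(l) {
        idx <- which(labels == l)
        sample(idx, max(1, round(0.2 * length(idx))))
      }))
      list(train = setdiff(seq_along(labels), te), test = sort(te))
    }),
    fixed_test = {
      if (is.null(test)) stop("scheme 'fixed_test' requires a test set")
      list(list(train = seq_along(labels), test = NULL))
    })

  per_fold <- data.frame(fold = integer(), acc = numeric(), kappa = numeric(),
                         auc = numeric())
  pooled_true <- factor(character(), levels = lv)
  pooled_pred <- factor(character(), levels = lv)
  pooled_scores <- NULL
  for (f in seq_along(splits)) {
    tr <- splits[[f]]$train
    if (scheme == "fixed_test") {
      xte <- as.matrix(test$x); yte <- factor(test$labels, levels = lv)
    } else {
      te <- splits[[f]]$test
      xte <- x[te, , drop = FALSE]; yte <- labels[te]
    }
    if (length(unique(labels[tr])) < length(lv))
      stop("a class is absent from a training fold; reduce k or rebalance")
    st <- standardize_fit(x[tr, , drop = FALSE])
    model <- fit_lda(standardize_apply(x[tr, , drop = FALSE], st), labels[tr])
    pr <- predict(model, standardize_apply(xte, st))
    cm <- table(truth = yte, pred = pr$class)
    auc_sc <- if (length(lv) == 2) pr$scores[, 2] - pr$scores[, 1] else pr$scores
    per_fold <- rbind(per_fold, data.frame(
      fold = f, acc = 100 * mean(pr$class == yte),
      kappa = cohen_kappa(cm),
      auc = if (length(unique(yte)) < 2) NA_real_ else auc_score(auc_sc, yte)))
    pooled_true <- c(pooled_true, yte)
    pooled_pred <- c(pooled_pred, pr$class)
    pooled_scores <- rbind(pooled_scores, as.matrix(pr$scores))
  }
  confusion <- table(truth = pooled_true, pred = pooled_pred)
  pooled_auc_sc <- if (length(lv) == 2)
    pooled_scores[, 2] - pooled_scores[, 1] else pooled_scores
  res <- list(
    acc = 100 * sum(diag(confusion)) / sum(confusion),
    kappa = cohen_kappa(confusion),
    auc = auc_score(pooled_auc_sc, pooled_true),
    confusion = confusion,
    per_fold = per_fold,
    mean_sd = data.frame(
      metric = c("acc", "kappa", "auc"),
      mean = c(mean(per_fold$acc), mean(per_fold$kappa),
               mean(per_fold$auc, na.rm = TRUE)),
      sd = c(stats::sd(per_fold$acc), stats::sd(per_fold$kappa),
             stats::sd(per_fold$auc, na.rm = TRUE))),
    scheme = scheme, seed = seed)
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> scheme=%s  ACC=%.1f%%  kappa=%.3f  AUC=%.3f  (%d fold(s))\n",
              x$scheme, x$acc, x$kappa, x$auc, nrow(x$per_fold)))
  invisible(x)
}
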