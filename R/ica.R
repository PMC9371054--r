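#' High-pass filter trials before ICA
#'
#' Zero-phase (forward-backward) fifth-order Butterworth high-pass at
#' `cutoff_hz`, applied per channel and per trial, removing the low-frequency
#' drifts that degrade ICA decompositions.
#'
#' @param trials a [trialset()].
#' @param cutoff_hz cutoff frequency, default 1 Hz.
#' @return The filtered `trialset`; reference traces, if any, are filtered
#'   identically so component scoring stays sample-aligned.
#' @export
highpass_for_ica <- function(trials, cutoff_hz = 1) {
  stopifnot(inherits(trials, "trialset"))
  if (trials$fs <= 2) stop("sampling rate too low for a 1 Hz high-pass")
  order <- 5L
  if (n_samples(trials) < 3 * (2 * order + 1))
    stop("trials shorter than the filter warm-up (3x filter length)")
  b <- signal::butter(order, cutoff_hz / (trials$fs / 2), type = "high")
  filt_tensor <- function(a) {
    for (t in seq_len(dim(a)[1]))
      for (c in seq_len(dim(a)[2]))
        a[t, c, ] <- signal::filtfilt(b, a[t, c, ])
    a
  }
  trials$data <- filt_tensor(trials$data)
  if (!is.null(trials$refs)) trials$refs <- filt_tensor(trials$refs)
  trials
}

#' Negentropy FastICA on trial-concatenated EEG
#'
#' Whitens the channel-concatenated data and runs deflation FastICA with the
#' Gaussian contrast `g(u) = u exp(-u^2 / 2)` (the standard approximation of
#' the negentropy cost), extracting as many components as channels one at a
#' time with Gram-Schmidt orthogonalization. Unmixing rows are unit-norm in
#' whitened space, so source rows have unit variance. Components carrying only
#' Gaussian noise have no identifiable direction and may not converge; the
#' best iterate is kept with a warning. The decomposition is deterministic
#' given `seed`.
#'
#' @param trials a [trialset()], normally already high-passed.
#' @param seed integer seed for the random orthogonal initialization.
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @return An object of class `ica_decomposition`: `mixing_W` (channels x Q
#'   back-projection), `sources_S` (Q x total samples), `whitening`,
#'   `channel_means`, `n_components_Q`, `n_trials`, `n_samples`, `converged`.
#' @export
fit_fastica <- function(trials, seed = 0, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(trials, "trialset"))
  C <- n_channels(trials)
  X <- t(apply(trials$data, 2, function(m) as.vector(t(m))))  # C x (trials*T)
  dim(X) <- c(C, n_trials(trials) * n_samples(trials))
  if (ncol(X) < 10 * C^2)
    stop("need at least 10 * channels^2 concatenated samples for a stable fit")
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  d <- pmax(eg$values, .Machine$double.eps)
  K <- diag(1 / sqrt(d)) %*% t(eg$vectors)      # whitening, Q x C
  Z <- K %*% Xc                                 # whitened data

  set.seed(seed)
  W <- matrix(0, C, C)                          # unmixing rows, whitened space
  n_conv <- 0L
  for (q in seq_len(C)) {
    w <- stats::rnorm(C)
    ortho <- function(v) {                      # Gram-Schmidt vs earlier rows
      if (q > 1) {
        Wp <- W[seq_len(q - 1), , drop = FALSE]
        v <- v - drop(crossprod(Wp, Wp %*% v))
      }
      v / sqrt(sum(v^2))
    }
    w <- ortho(w)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      u <- drop(w %*% Z)
      w_new <- ortho(drop(Z %*% (u * exp(-u^2 / 2))) / ncol(Z) -
                       mean((1 - u^2) * exp(-u^2 / 2)) * w)
      delta <- abs(1 - abs(sum(w_new * w)))
      w <- w_new
      if (delta < tol) { conv <- TRUE; break }
    }
    n_conv <- n_conv + conv
    W[q, ] <- w
  }
  converged <- n_conv == C
  if (!converged)
    warning(sprintf("FastICA: %d of %d components did not converge; best iterates kept",
                    C - n_conv, C))
  S <- W %*% Z                                  # unit-variance source rows
  # back-projection to sensor space: X = A S + mu, A = E D^{1/2} W'
  A <- eg$vectors %*% diag(sqrt(d)) %*% t(W)
  structure(list(mixing_W = A, sources_S = S, whitening = K,
                 unmixing = W %*% K, channel_means = mu,
                 n_components_Q = C, n_trials = n_trials(trials),
                 n_samples = n_samples(trials), converged = converged),
            class = "ica_decomposition")
}

#' Score ICA components against artifact reference traces
#'
#' Pearson-correlates every ICA source with every reference trace, trial by
#' trial, and aggregates by the mean of absolute correlations across trials
#' (robust to trial-wise sign flips). Zero-variance segments score 0 with a
#' warning.
#'
#' @param ica an `ica_decomposition`.
#' @param references refs x total-samples matrix, sample-aligned with
#'   `ica$sources_S` (trial-concatenated).
#' @return Q x refs matrix of aggregated absolute correlations, with attribute
#'   `per_trial` (Q x refs x trials array of signed per-trial correlations).
#' @export
score_components <- function(ica, references) {
  references <- rbind(references)
  if (ncol(references) != ncol(ica$sources_S))
    stop("references must be sample-aligned with the ICA sources")
  Q <- ica$n_components_Q; R <- nrow(references); Tn <- ica$n_samples
  per_trial <- array(0, c(Q, R, ica$n_trials))
  warned <- FALSE
  for (t in seq_len(ica$n_trials)) {
    idx <- (t - 1) * Tn + seq_len(Tn)
    s_seg <- ica$sources_S[, idx, drop = FALSE]
    r_seg <- references[, idx, drop = FALSE]
    sv <- apply(s_seg, 1, stats::sd); rv <- apply(r_seg, 1, stats::sd)
    if (any(sv == 0) || any(rv == 0)) warned <- TRUE
    for (q in seq_len(Q)) for (r in seq_len(R)) {
      per_trial[q, r, t] <- if (sv[q] == 0 || rv[r] == 0) 0 else
        stats::cor(s_seg[q, ], r_seg[r, ])
    }
  }
  if (warned) warning("zero-variance component or reference segment; score set to 0")
  scores <- apply(abs(per_trial), c(1, 2), mean)
  attr(scores, "per_trial") <- per_trial
  scores
}

#' Three-sigma rejection threshold on pooled component scores
#'
#' Z-scores the pooled per-component scores (maximum absolute correlation over
#' references) and returns the value on the original correlation scale
#' corresponding to z = 3. Components scoring above the threshold are marked as
#' artifacts.
#'
#' @param scores Q x refs score matrix from [score_components()] (or a vector
#'   of per-component scores).
#' @return An object of class `rejection_mask`: `keep` (logical per component),
#'   `gamma` (threshold on the correlation scale), `score` (per-component
#'   pooled score), `z` (z-scored values).
#' @export
threshold_3sigma <- function(scores) {
  # matrix input: pool by the maximum |corr| over references; vector input is
  # taken as already-pooled scores
  s <- if (is.matrix(scores)) apply(abs(scores), 1, max) else as.numeric(scores)
  if (sum(is.finite(s)) < 2) stop("need at least 2 finite scores")
  sdv <- stats::sd(s)
  if (sdv == 0) {
    warning("zero variance of component scores; no component rejected")
    gamma <- Inf
    z <- rep(0, length(s))
  } else {
    z <- (s - mean(s)) / sdv
    gamma <- mean(s) + 3 * sdv
  }
  structure(list(keep = !(s > gamma), gamma = gamma, score = s, z = z),
            class = "rejection_mask")
}

#' Reconstruct trials with rejected components zeroed
#'
#' Projects every trial through the decomposition with the rejected source
#' rows zeroed: `X~ = A diag(keep) W_unmix (X - mu) + mu`. Because the
#' unmixing is computed from the trial data rather than the stored sources,
#' the cleaning learned on one set of trials (e.g. a training portion) can be
#' applied to any trials of the same montage. With every component kept this
#' reproduces the input (within numerical round-off), and the operation is a
#' projection: applying it twice with the same mask equals applying it once.
#'
#' @param trials a [trialset()] with the channel count the decomposition was
#'   fitted on.
#' @param ica an `ica_decomposition`.
#' @param mask a `rejection_mask` (or logical keep vector of length Q).
#' @return The reconstructed `trialset`.
#' @export
remove_and_reconstruct <- function(trials, ica, mask) {
  keep <- if (inherits(mask, "rejection_mask")) mask$keep else as.logical(mask)
  if (length(keep) != ica$n_components_Q) stop("mask length must equal Q")
  if (!any(keep)) stop("all components rejected; refusing to return all-zero data")
  if (n_channels(trials) != nrow(ica$mixing_W)) stop("channel count mismatch")
  P <- ica$mixing_W %*% (keep * ica$unmixing)   # C x C cleaning projector
  out <- trials$data
  for (t in seq_len(n_trials(trials)))
    out[t, , ] <- P %*% (trials$data[t, , ] - ica$channel_means) +
      ica$channel_means
  with_data(trials, out)
}

# Assemble the trial-concatenated reference matrix for scoring.
reference_matrix <- function(trials, ref_mode) {
  if (ref_mode == "eog") {
    if (is.null(trials$refs)) stop("ref_mode 'eog' but no reference traces attached")
    r <- trials$refs
  } else {
    fi <- frontal_indices(trials$positions, 3)
    r <- trials$data[, fi, , drop = FALSE]
  }
  out <- matrix(0, dim(r)[2], dim(r)[1] * dim(r)[3])
  Tn <- dim(r)[3]
  for (t in seq_len(dim(r)[1]))
    out[, (t - 1) * Tn + seq_len(Tn)] <- r[t, , ]
  out
}

#' ICA-based ocular artifact cleaning (full cycle, two passes)
#'
#' Runs the complete pipeline: 1 Hz high-pass, FastICA fit on the
#' trial-concatenated data, per-trial correlation scoring against the artifact
#' references (dedicated EOG traces or the three frontal electrodes), 3-sigma
#' thresholding, and reconstruction without the rejected components. The
#' fit-score-reject-reconstruct cycle is performed `passes` times sequentially
#' (default twice), each pass on the previous pass's output.
#'
#' @param trials a [trialset()].
#' @param ref_mode `"frontal"` (default) scores against the three most anterior
#'   electrodes of the current data; `"eog"` uses `trials$refs`.
#' @param seed FastICA seed (pass k uses `seed + k - 1`).
#' @param passes number of full cycles (default 2).
#' @param highpass apply the 1 Hz high-pass before the first pass (default
#'   TRUE); the high-passed signal is what is cleaned and passed downstream.
#' @param fit_idx trial indices used for fitting and scoring the
#'   decomposition (default: all); the learned cleaning is applied to every
#'   trial, so held-out trials never influence the fit.
#' @return The cleaned `trialset`, with attribute `rejections`: one data frame
#'   per pass listing rejected components, their scores and the threshold.
#' @export
ica_clean <- function(trials, ref_mode = c("frontal", "eog"), seed = 0,
                      passes = 2, highpass = TRUE, fit_idx = NULL) {
  ref_mode <- match.arg(ref_mode)
  cur <- if (highpass) highpass_for_ica(trials) else trials
  if (is.null(fit_idx)) fit_idx <- seq_len(n_trials(trials))
  log <- vector("list", passes)
  pass_scores <- vector("list", passes)
  for (k in seq_len(passes)) {
    fit_trials <- cur[fit_idx]
    ica <- fit_fastica(fit_trials, seed = seed + k - 1)
    refs <- reference_matrix(fit_trials, ref_mode)
    scores <- score_components(ica, refs)
    mask <- threshold_3sigma(scores)
    rej <- which(!mask$keep)
    log[[k]] <- data.frame(pass = rep(k, length(rej)), component = rej,
                           score = mask$score[rej],
                           gamma = rep(mask$gamma, length(rej)))
    pass_scores[[k]] <- mask$score
    if (!all(mask$keep)) cur <- remove_and_reconstruct(cur, ica, mask)
  }
  attr(cur, "rejections") <- do.call(rbind, log)
  attr(cur, "pass_scores") <- pass_scores
  cur
}
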