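#' Partition subjects into three skill groups by k-means
#'
#' Clusters a per-subject performance metric (accuracy, kappa or AUC computed
#' under the raw scenario) with k-means and relabels the clusters by
#' descending centroid, so GI holds the best performers and GIII the poorest.
#' Identical metrics across subjects make the partition meaningless and raise
#' an error rather than silently collapsing groups.
#'
#' @param metric_per_subject named numeric vector, one metric value per
#'   subject.
#' @param k number of groups (default 3).
#' @param seed integer seed for the k-means restarts.
#' @param nstart restarts (default 20).
#' @return An object of class `skill_partition`: `group_of` (factor
#'   `GI`/`GII`/`GIII` per subject), `centroids` (descending), `metric`.
#' @export
kmeans_skill_groups <- function(metric_per_subject, k = 3, seed = 0,
                                nstart = 20) {
  m <- as.numeric(metric_per_subject)
  if (length(m) < k) stop("fewer subjects than groups")
  if (length(unique(m)) < k)
    stop("degenerate clustering: fewer distinct metric values than groups")
  set.seed(seed)
  km <- stats::kmeans(matrix(m, ncol = 1), centers = k, nstart = nstart)
  ord <- order(km$centers[, 1], decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  grp <- factor(paste0("G", c("I", "II", "III", as.character(4:9))[relabel[km$cluster]]),
                levels = paste0("G", c("I", "II", "III", as.character(4:9))[seq_len(k)]))
  names(grp) <- names(metric_per_subject)
  structure(list(group_of = grp, centroids = sort(km$centers[, 1],
                                                  decreasing = TRUE),
                 metric = metric_per_subject, seed = seed),
            class = "skill_partition")
}

#' @export
print.skill_partition <- function(x, ...) {
  cat("<skill_partition> centroids:",
      paste(sprintf("%.1f", x$centroids), collapse = " > "), "\n")
  print(table(x$group_of))
  invisible(x)
}

#' Connectivity-link relevance from LDA coefficients
#'
#' Maps the absolute LDA coefficients of a model trained on the 4-band FC
#' feature vector to per-link relevance weights: the class-wise coefficient
#' vectors are collapsed by the element-wise maximum of absolute values,
#' min-max normalized to `[0, 1]`, and the three beta sub-band blocks merged
#' element-wise by the maximum, yielding a mu block plus a merged beta block
#' of total length `C * (C - 1)`.
#'
#' @param model an `lda_model` from [fit_lda()] trained on a feature matrix
#'   from [build_features()].
#' @param pair_index the `pair_index` attribute of that feature matrix.
#' @return An object of class `relevance_map`: `per_band_weights` (length
#'   `4 C (C-1) / 2`), `merged_weights` (length `C (C-1)`, named mu/beta), and
#'   the merged `pairs` table.
#' @export
relevance_from_lda <- function(model, pair_index) {
  co <- abs(as.matrix(coef(model)))
  w <- apply(co, 1, max)
  if (length(w) != nrow(pair_index))
    stop("coefficient length does not match pair_index")
  if (max(w) == 0) {
    warning("all-zero LDA coefficients; relevance map is all-zero")
  } else {
    w <- (w - min(w)) / (max(w) - min(w))
  }
  bands <- unique(pair_index$band)
  mu_block <- w[pair_index$band == bands[1]]
  beta <- sapply(bands[-1], function(b) w[pair_index$band == b])
  beta_block <- apply(beta, 1, max)
  merged <- c(mu_block, beta_block)
  pairs <- rbind(
    data.frame(rhythm = "mu", pair_index[pair_index$band == bands[1], c("i", "j")]),
    data.frame(rhythm = "beta", pair_index[pair_index$band == bands[2], c("i", "j")]))
  structure(list(per_band_weights = w, merged_weights = merged, pairs = pairs),
            class = "relevance_map")
}

#' Group-level relevance summary
#'
#' Stacks the merged relevance vectors of every subject in a skill group and
#' reports the per-link maxima together with the links whose group maximum
#' exceeds the threshold (0.9 by default) — the links contributing most to
#' discrimination within that group.
#'
#' @param maps named list of `relevance_map` objects, one per subject.
#' @param partition a `skill_partition` over the same subjects.
#' @param group group label (`"GI"`, `"GII"`, `"GIII"`).
#' @param link_threshold relevance cutoff for reported links (default 0.9).
#' @return A list: `group`, `n_subjects`, `max_weights` (per-link maxima),
#'   `links` (data frame of above-threshold links), `threshold`.
#' @export
group_relevance <- function(maps, partition, group, link_threshold = 0.9) {
  members <- names(partition$group_of)[partition$group_of == group]
  if (length(members) == 0) stop("empty group: ", group)
  mat <- do.call(rbind, lapply(maps[members], function(m) m$merged_weights))
  if (is.null(mat)) stop("no relevance maps found for group members")
  mx <- apply(mat, 2, max)
  pairs <- maps[[members[1]]]$pairs
  sel <- which(mx > link_threshold)
  list(group = group, n_subjects = length(members), max_weights = mx,
       links = cbind(pairs[sel, , drop = FALSE], weight = mx[sel]),
       threshold = link_threshold)
}
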