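#' Epoched EEG trial set
#'
#' A `trialset` bundles an epoched EEG tensor with its montage and labels. It is
#' the object every preprocessing stage maps to itself: `data` is a numeric
#' array of dimension trials x channels x samples (microvolts), `positions`
#' holds the electrode coordinates on a unit-radius sphere, and `labels` is a
#' factor with one level per motor-imagery class.
#'
#' @param data numeric array, trials x channels x samples, no missing values.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per channel.
#' @param positions numeric matrix channels x 3; every row must have unit norm.
#' @param labels factor (or coercible) of length trials.
#' @param window numeric length-2, epoch window in seconds relative to cue
#'   onset; the first sample of `data` corresponds to `window[1]`.
#' @param refs optional numeric array trials x n_refs x samples of artifact
#'   reference traces (e.g. EOG channels), sample-aligned with `data`.
#'
#' @return An object of class `trialset`.
#' @export
trialset <- function(data, fs, channel_names = NULL, positions = NULL,
                     labels = NULL, window = c(0, dim(data)[3] / fs),
                     refs = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (anyNA(data)) stop("trialset data must not contain missing values")
  n_tr <- dim(data)[1]; n_ch <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(n_ch))
  if (length(channel_names) != n_ch) stop("channel_names length must equal channel count")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != n_ch || ncol(positions) != 3L)
      stop("positions must be a channels x 3 matrix")
    nrm <- sqrt(rowSums(positions^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("every electrode position must lie on the unit sphere (|norm - 1| <= 1e-9)")
  }
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != n_tr) stop("labels length must equal trial count")
  }
  if (!is.null(refs)) {
    stopifnot(is.array(refs), length(dim(refs)) == 3L,
              dim(refs)[1] == n_tr, dim(refs)[3] == dim(data)[3])
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         positions = positions, labels = labels,
         window = as.numeric(window), refs = refs),
    class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window: [%g, %g) s relative to cue\n", x$window[1], x$window[2]))
  if (!is.null(x$labels))
    cat("  classes:", paste(sprintf("%s (%d)", levels(x$labels),
                                    tabulate(x$labels)), collapse = ", "), "\n")
  if (!is.null(x$refs))
    cat(sprintf("  %d artifact reference trace(s) attached\n", dim(x$refs)[2]))
  invisible(x)
}

#' @rdname trialset
#' @param x a `trialset`.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname trialset
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname trialset
#' @export
n_samples <- function(x) dim(x$data)[3]

# Replace the data tensor, keeping all metadata.
with_data <- function(x, data) {
  stopifnot(identical(dim(data)[1:2], dim(x$data)[1:2]))
  x$data <- data
  x
}

#' Subset trials of a trial set
#'
#' @param x a `trialset`.
#' @param i trial indices.
#' @param ... ignored.
#' @export
`[.trialset` <- function(x, i, ...) {
  x$data <- x$data[i, , , drop = FALSE]
  if (!is.null(x$labels)) x$labels <- droplevels(x$labels[i])
  if (!is.null(x$refs)) x$refs <- x$refs[i, , , drop = FALSE]
  x
}

#' Read and write the interchange format
#'
#' One file per subject holding the data tensor, labels, sampling rate, channel
#' names, electrode positions, epoch window and any reference traces. The
#' round-trip is lossless (bit-identical tensors).
#'
#' @param x a `trialset`.
#' @param path file path (conventionally `.rds`).
#' @return `write_trialset` returns `path` invisibly; `read_trialset` returns
#'   the stored `trialset`.
#' @export
write_trialset <- function(x, path) {
  stopifnot(inherits(x, "trialset"))
  saveRDS(unclass(x), path)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  obj <- readRDS(path)
  do.call(trialset, obj[c("data", "fs", "channel_names", "positions",
                          "labels", "window", "refs")])
}

#' Frontal electrode indices of a montage
#'
#' Returns the indices of the `n` most anterior electrodes (largest y
#' coordinate), the montage's designated ocular-artifact reference sensors when
#' no dedicated EOG channels were recorded.
#'
#' @param positions channels x 3 unit-sphere coordinates (y axis = anterior).
#' @param n number of frontal electrodes (default 3).
#' @export
frontal_indices <- function(positions, n = 3) {
  order(positions[, 2], decreasing = TRUE)[seq_len(n)]
}

# Index of the electrode closest to the vertex (0, 0, 1); Cz-like.
central_index <- function(positions) {
  which.max(positions[, 3])
}
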