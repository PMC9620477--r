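#' Labeled multichannel EEG epochs
#'
#' The central data container: a numeric array of `n_epochs x n_channels x
#' n_samples` (microvolts) plus sampling rate, montage, per-epoch class
#' labels, optional per-epoch valence/arousal ratings (1-9 scale) and a
#' subject identifier. Channel order is montage order everywhere; features
#' are indexed by channel label, never raw position.
#'
#' @param data Numeric array `[n_epochs, n_channels, n_samples]`.
#' @param fs Sampling rate in Hz (> 0).
#' @param montage A [montage] whose channel count matches `dim(data)[2]`.
#' @param labels Per-epoch class labels (character or factor),
#'   length `n_epochs`.
#' @param ratings Optional data frame with columns `valence`, `arousal`
#'   (one row per epoch), or `NULL`.
#' @param subject_id Identifier string.
#' @return An `epoch_set` object.
#' @examples
#' m <- montage_preset("deap")
#' x <- array(rnorm(2 * 32 * 64), c(2, 32, 64))
#' es <- epoch_set(x, fs = 128, montage = m, labels = c("high", "low"))
#' n_epochs(es)
#' @export
epoch_set <- function(data, fs, montage, labels,
                      ratings = NULL, subject_id = "S01") {
  if (length(dim(data)) != 3) stop("epoch_set: data must be a 3-d array [epochs x channels x samples]")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("epoch_set: fs must be a positive scalar")
  if (!inherits(montage, "montage")) stop("epoch_set: montage must be a montage object")
  if (dim(data)[2] != length(montage$channel_labels)) {
    stop("epoch_set: data has ", dim(data)[2], " channels but montage has ",
         length(montage$channel_labels))
  }
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1]) stop("epoch_set: one label per epoch required")
  if (!is.null(ratings)) {
    ratings <- tibble::as_tibble(ratings)
    stopifnot(all(c("valence", "arousal") %in% names(ratings)))
    if (nrow(ratings) != dim(data)[1]) stop("epoch_set: one rating row per epoch required")
  }
  structure(
    list(data = data, fs = fs, montage = montage, labels = labels,
         ratings = ratings, subject_id = as.character(subject_id)),
    class = "epoch_set"
  )
}

#' @rdname epoch_set
#' @param x An `epoch_set`.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' @rdname epoch_set
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname epoch_set
#' @export
n_samples <- function(x) dim(x$data)[3]

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> subject ", x$subject_id, ": ",
      n_epochs(x), " epochs x ", n_channels(x), " channels x ",
      n_samples(x), " samples @ ", x$fs, " Hz\n", sep = "")
  tab <- table(x$labels)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$ratings)) cat("  ratings: valence/arousal present\n")
  invisible(x)
}

#' Subset an epoch_set by epochs
#'
#' @param x An `epoch_set`.
#' @param i Epoch indices (integer or logical).
#' @return An `epoch_set` with the selected epochs, labels and ratings.
#' @export
subset_epochs <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$fs, x$montage, x$labels[i],
            ratings = if (is.null(x$ratings)) NULL else x$ratings[i, , drop = FALSE],
            subject_id = x$subject_id)
}

#' Subset an epoch_set by channel labels
#'
#' Keeps the given channels (montage order preserved); symmetric pairs with
#' a missing member are dropped from the resulting montage.
#'
#' @param x An `epoch_set`.
#' @param channels Character vector of channel labels to keep.
#' @return An `epoch_set` on the reduced montage.
#' @export
subset_channels <- function(x, channels) {
  stopifnot(inherits(x, "epoch_set"))
  keep <- x$montage$channel_labels %in% channels
  if (!any(keep)) stop("subset_channels: no requested channel present")
  missing <- setdiff(channels, x$montage$channel_labels)
  if (length(missing)) stop("subset_channels: unknown channels: ",
                            paste(missing, collapse = ", "))
  labs <- x$montage$channel_labels[keep]
  pr <- x$montage$symmetric_pairs
  pr <- pr[pr[, 1] %in% labs & pr[, 2] %in% labs, , drop = FALSE]
  m2 <- montage(labs, pr, x$montage$region_map[labs])
  epoch_set(x$data[, keep, , drop = FALSE], x$fs, m2, x$labels,
            ratings = x$ratings, subject_id = x$subject_id)
}

# matrix [channels x samples] for one epoch
epoch_matrix <- function(x, i) {
  m <- x$data[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}
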