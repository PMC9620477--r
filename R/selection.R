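# mRMR feature selection: plug-in mutual information after equal-frequency
# discretization, greedy MID (relevance minus mean redundancy) ranking,
# and cross-subject electrode frequency counting. Tie-breaks everywhere
# are "lowest column index / montage order" for reproducibility.

# Equal-frequency discretization into at most n_bins levels. Constant
# vectors collapse to a single level.
discretize_ef <- function(x, n_bins = 8) {
  r <- rank(x, ties.method = "average")
  ceiling(r * n_bins / (length(x) + 1e-9))
}

mi_table <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual information between a feature and labels
#'
#' Plug-in mutual information (nats) between an equal-frequency
#' discretized continuous feature and a categorical label. Invariant under
#' strictly monotone transforms of the feature (rank-based binning);
#' constant features give 0.
#'
#' @param x Numeric feature vector.
#' @param y Labels (character/factor), at least 2 classes for a
#'   non-trivial value.
#' @param n_bins Number of equal-frequency bins (default 8).
#' @param y_continuous Treat `y` as a continuous feature and discretize it
#'   the same way as `x` (used for feature-feature redundancy terms).
#' @return Mutual information in nats (`>= 0`).
#' @export
mutual_information <- function(x, y, n_bins = 8, y_continuous = FALSE) {
  if (length(x) != length(y)) stop("mutual_information: length mismatch")
  if (any(!is.finite(x))) stop("mutual_information: non-finite feature values")
  b <- if (y_continuous) discretize_ef(as.numeric(y), n_bins) else as.character(y)
  mi <- mi_table(discretize_ef(x, n_bins), b)
  max(mi, 0)
}

#' Greedy mRMR feature ranking
#'
#' Ranks feature columns by the minimum-redundancy maximum-relevance
#' criterion (MID, mutual-information difference): the first feature
#' maximizes relevance `MI(f; y)`; each subsequent feature maximizes
#' `MI(f; y) - mean(MI(f; selected))`. Feature-feature MI uses the same
#' equal-frequency discretization as feature-label MI. Ties break toward
#' the lowest column index.
#'
#' @param data A data frame / feature matrix of numeric columns.
#' @param labels Per-row class labels.
#' @param k Number of features to rank (`1..ncol(data)`).
#' @param n_bins Discretization bins.
#' @param variant `"mid"` (difference, default) or `"miq"` (quotient).
#' @return Integer vector of column indices, length `k`, in selection
#'   order.
#' @export
mrmr_rank <- function(data, labels, k = ncol(data), n_bins = 8,
                      variant = c("mid", "miq")) {
  variant <- match.arg(variant)
  X <- as.matrix(data)
  if (k <= 0) stop("mrmr_rank: k must be positive")
  if (k > ncol(X)) stop("mrmr_rank: k exceeds number of features")
  y <- as.character(labels)
  if (length(unique(y)) < 2) stop("mrmr_rank: need at least 2 classes")
  nb <- n_bins
  disc <- apply(X, 2, discretize_ef, n_bins = nb)
  rel <- vapply(seq_len(ncol(X)), function(j) mi_table(disc[, j], y), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(ncol(X))
  red_sum <- numeric(ncol(X))
  for (step in seq_len(k)) {
    if (step == 1) {
      score <- rel[remaining]
    } else {
      jnew <- selected[length(selected)]
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) mi_table(disc[, j], disc[, jnew]), numeric(1))
      red_mean <- red_sum[remaining] / length(selected)
      score <- if (variant == "mid") rel[remaining] - red_mean
               else rel[remaining] / pmax(red_mean, .Machine$double.eps)
    }
    pick <- remaining[which.max(score)]  # which.max: first max -> lowest index
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Cross-subject electrode frequency counting
#'
#' Given per-subject mRMR rankings of per-electrode feature columns,
#' counts how often each electrode occurs in the subjects' top-`k` and
#' returns the `k` most frequently selected electrodes (ties broken by
#' montage order).
#'
#' @param rankings A list (one element per subject) of character vectors
#'   of electrode labels in ranked order, or of integer indices into
#'   `electrodes`.
#' @param k Top-list size.
#' @param electrodes Montage-ordered electrode labels (defines the
#'   tie-break order and the count table rows).
#' @return A list with `counts` (tibble `electrode`, `count`, montage
#'   order) and `top` (character vector of the `k` chosen electrodes).
#' @export
electrode_frequency <- function(rankings, k, electrodes) {
  counts <- stats::setNames(rep(0L, length(electrodes)), electrodes)
  for (r in rankings) {
    if (is.numeric(r)) r <- electrodes[r]
    if (length(r) < k) stop("electrode_frequency: a ranking is shorter than k")
    top <- unique(r)[seq_len(k)]
    counts[top] <- counts[top] + 1L
  }
  ord <- order(-counts, seq_along(electrodes))
  list(
    counts = tibble::tibble(electrode = electrodes, count = as.integer(counts)),
    top = electrodes[ord][seq_len(k)]
  )
}

#' Per-subject mRMR electrode selection over a cohort
#'
#' For each subject's feature matrix, restricts to the columns of one
#' per-electrode base feature, ranks electrodes with [mrmr_rank()], then
#' counts electrode frequencies across subjects for each requested subset
#' size. This mirrors the important-electrode analysis: per-feature,
#' per-subject rankings aggregated into cohort-level key electrodes.
#'
#' @param fms List of `feature_matrix` objects (one per subject).
#' @param family,feature,band Select the base feature whose per-electrode
#'   columns are ranked (e.g. `family = "timefreq"`, `feature = "de"`,
#'   `band = "high_gamma"`).
#' @param sizes Electrode-subset sizes (default `c(1, 4, 8, 16)`).
#' @param n_bins Discretization bins for mutual information.
#' @return A `selection_result`: list with `rankings` (per subject
#'   electrode label vectors), `counts` (per-size tibbles) and `sets`
#'   (per-size electrode vectors).
#' @export
select_electrodes <- function(fms, family, feature, band = NA,
                              sizes = c(1, 4, 8, 16), n_bins = 8) {
  meta <- column_meta(fms[[1]])
  sel <- meta$family == family & meta$feature == feature &
    (if (is.na(band)) is.na(meta$band) else !is.na(meta$band) & meta$band == band)
  if (!any(sel)) stop("select_electrodes: no columns match the base feature")
  ids <- meta$id[sel]
  electrodes <- meta$electrode[sel]
  rankings <- lapply(fms, function(fm) {
    idx <- mrmr_rank(fm[, ids, drop = FALSE], epoch_labels(fm),
                     k = length(ids), n_bins = n_bins)
    electrodes[idx]
  })
  sizes <- sizes[sizes <= length(electrodes)]
  counts <- list(); sets <- list()
  for (k in sizes) {
    ef <- electrode_frequency(rankings, k, electrodes)
    counts[[as.character(k)]] <- ef$counts
    sets[[as.character(k)]] <- ef$top
  }
  structure(list(rankings = rankings, counts = counts, sets = sets,
                 feature = c(family = family, feature = feature, band = band)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> base feature:",
      paste(stats::na.omit(x$feature), collapse = "/"), "\n")
  for (k in names(x$sets)) {
    cat("  top-", k, ": ", paste(x$sets[[k]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname select_electrodes
#' @param object A `selection_result`.
#' @param ... Unused.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy(object)
  df$electrode <- factor(df$electrode, levels = unique(df$electrode))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$electrode, y = .data$count,
                                   fill = .data$in_top)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~size, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "subjects selecting electrode", x = NULL, fill = "in top set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname select_electrodes
#' @param x A `selection_result`.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$counts), function(k) {
    dplyr::mutate(x$counts[[k]], size = as.integer(k),
                  in_top = .data$electrode %in% x$sets[[k]])
  }))
}
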