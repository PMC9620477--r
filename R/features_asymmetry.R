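# Spatial asymmetry features: for every per-electrode base feature and
# every homologous (left, right) electrode pair, DA = fea_left - fea_right
# and RA = fea_left / fea_right.

#' Differential and rational asymmetry features
#'
#' Derives DA (left minus right) and RA (left over right) columns from the
#' per-electrode base features of a feature matrix, one column per
#' homologous electrode pair of the montage. The base features are all
#' per-electrode time, frequency and time-frequency columns present in
#' `fm` (configurable via `base_features`).
#'
#' RA is passed through with its sign: a signed base feature (for example
#' a DA of differences) can yield negative ratios. A zero right-hemisphere
#' value makes RA undefined for that epoch; it is returned as `NA` with a
#' warning rather than as an infinity.
#'
#' @param fm A `feature_matrix` from [extract_features()].
#' @param montage The [montage] supplying `symmetric_pairs`.
#' @param which `"DA"`, `"RA"` or both.
#' @param base_features Optional subset of base feature rows (a data frame
#'   with columns `family`, `feature`, `band`) to derive asymmetries from.
#' @return The feature matrix with asymmetry columns appended.
#' @export
add_asymmetry_features <- function(fm, montage, which = c("DA", "RA"),
                                   base_features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(montage, "montage"))
  which <- match.arg(which, several.ok = TRUE)
  meta <- column_meta(fm)
  per_el <- meta[meta$family %in% c("time", "frequency", "timefreq"), ]
  feats <- dplyr::distinct(per_el[, c("family", "feature", "band")])
  if (!is.null(base_features)) {
    feats <- dplyr::semi_join(feats, tibble::as_tibble(base_features),
                              by = intersect(names(feats), names(base_features)))
  }
  pairs <- montage$symmetric_pairs
  if (!nrow(pairs)) stop("add_asymmetry_features: montage has no symmetric pairs")
  vals <- as.matrix(fm)
  new_cols <- list()
  new_meta <- list()
  ra_zero <- FALSE
  for (r in seq_len(nrow(feats))) {
    fam <- feats$family[r]; fe <- feats$feature[r]; bd <- feats$band[r]
    lid <- feature_id(fam, fe, bd, pairs[, 1])
    rid <- feature_id(fam, fe, bd, pairs[, 2])
    missing <- c(lid, rid)[!(c(lid, rid) %in% meta$id)]
    if (length(missing)) {
      stop("add_asymmetry_features: base columns missing for pair(s): ",
           paste(missing, collapse = ", "))
    }
    L <- vals[, lid, drop = FALSE]
    R <- vals[, rid, drop = FALSE]
    pname <- paste(pairs[, 1], pairs[, 2], sep = "-")
    if ("DA" %in% which) {
      cols <- L - R
      colnames(cols) <- feature_id("DA", paste(fam, fe, sep = "."), bd, pname)
      new_cols[[length(new_cols) + 1]] <- cols
      new_meta[[length(new_meta) + 1]] <- tibble::tibble(
        family = "DA", feature = paste(fam, fe, sep = "."), band = bd,
        electrode = pname, id = colnames(cols))
    }
    if ("RA" %in% which) {
      zero <- !is.na(R) & R == 0
      if (any(zero)) ra_zero <- TRUE
      cols <- L / ifelse(zero, NA_real_, R)
      colnames(cols) <- feature_id("RA", paste(fam, fe, sep = "."), bd, pname)
      new_cols[[length(new_cols) + 1]] <- cols
      new_meta[[length(new_meta) + 1]] <- tibble::tibble(
        family = "RA", feature = paste(fam, fe, sep = "."), band = bd,
        electrode = pname, id = colnames(cols))
    }
  }
  if (ra_zero) warning("add_asymmetry_features: zero right-hemisphere value(s); RA set to NA")
  all_vals <- cbind(vals, do.call(cbind, new_cols))
  all_meta <- dplyr::bind_rows(c(list(meta), new_meta))
  new_feature_matrix(all_vals, all_meta, epoch_labels(fm), attr(fm, "subject_id"))
}

#' @rdname add_asymmetry_features
#' @export
differential_asymmetry <- function(fm, montage, base_features = NULL) {
  add_asymmetry_features(fm, montage, which = "DA", base_features = base_features)
}

#' @rdname add_asymmetry_features
#' @export
rational_asymmetry <- function(fm, montage, base_features = NULL) {
  add_asymmetry_features(fm, montage, which = "RA", base_features = base_features)
}
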