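#' Extract a feature matrix from labeled epochs
#'
#' Runs the registered feature families over every epoch and returns an
#' epochs-by-features tibble. Column order and identity follow
#' [feature_registry()]; per-electrode features are indexed by channel
#' label so montage subsetting is safe. Asymmetry families (DA/RA) are
#' derived from the per-electrode base features over the montage's
#' symmetric pairs.
#'
#' @param eps An [epoch_set].
#' @param families Feature families to compute (see [feature_registry()]).
#' @param bands A [band_scheme]; defaults to the 6-band scheme when the
#'   sampling rate allows 80 Hz, otherwise the 4-band scheme.
#' @param networks Connectivity methods for the network family.
#' @param entropy_m,entropy_r Embedding dimension and tolerance factor for
#'   approximate/sample entropy.
#' @param k_max Higuchi maximum sampling interval.
#' @param welch_window_s,stft_window_s,spectral_overlap Spectral analysis
#'   window settings (seconds / overlap fraction).
#' @return A `feature_matrix`: a tibble of feature columns with attributes
#'   `column_meta` (the registry rows), `labels` and `subject_id`.
#' @examples
#' es <- generate_subject(generator_spec("esd", n_trials_per_class = 2,
#'                                       epoch_length = 0.5), 1)
#' fm <- extract_features(es, families = "time")
#' dim(fm)
#' @export
extract_features <- function(eps,
                             families = c("time", "frequency", "timefreq",
                                          "network", "DA", "RA"),
                             bands = NULL,
                             networks = c("pearson", "coherence", "plv"),
                             entropy_m = 2, entropy_r = 0.2, k_max = 8,
                             welch_window_s = 1, stft_window_s = 0.5,
                             spectral_overlap = 0.5) {
  stopifnot(inherits(eps, "epoch_set"))
  families <- match.arg(families, several.ok = TRUE)
  if (is.null(bands)) {
    bands <- if (eps$fs / 2 > 80) band_scheme_preset("esd6") else band_scheme_preset("deap4")
  }
  if (any(bands$f_high > eps$fs / 2)) {
    bands <- band_scheme(bands[bands$f_high <= eps$fs / 2, ])
  }
  reg <- feature_registry(eps$montage, bands, families = families,
                          networks = networks)
  labs <- eps$montage$channel_labels
  nep <- n_epochs(eps)
  vals <- matrix(NA_real_, nep, nrow(reg))
  colnames(vals) <- reg$id
  base_reg <- reg[!(reg$family %in% c("DA", "RA")), ]

  for (e in seq_len(nep)) {
    m <- epoch_matrix(eps, e)
    row <- numeric(0)
    if ("time" %in% families) {
      for (ch in seq_along(labs)) {
        x <- m[ch, ]
        s <- feat_std(x)
        fd1 <- first_diff(x); fd2 <- second_diff(x)
        vals[e, feature_id("time", "std", NA, labs[ch])] <- s
        vals[e, feature_id("time", "fir_dif", NA, labs[ch])] <- fd1
        vals[e, feature_id("time", "sec_dif", NA, labs[ch])] <- fd2
        vals[e, feature_id("time", "n_fir_dif", NA, labs[ch])] <- if (s > 0) fd1 / s else NA_real_
        vals[e, feature_id("time", "n_sec_dif", NA, labs[ch])] <- if (s > 0) fd2 / s else NA_real_
        vals[e, feature_id("time", "fd", NA, labs[ch])] <-
          if (s > 0) higuchi_fd(x, k_max) else NA_real_
        vals[e, feature_id("time", "apen", NA, labs[ch])] <-
          approx_entropy(x, entropy_m, entropy_r)
        vals[e, feature_id("time", "samen", NA, labs[ch])] <-
          sample_entropy(x, entropy_m, entropy_r)
      }
    }
    if (any(c("frequency", "timefreq") %in% families)) {
      st <- stft_frames_multi(m, eps$fs, stft_window_s, spectral_overlap)
      est <- if ("frequency" %in% families) {
        welch_psd_multi(m, eps$fs, welch_window_s, spectral_overlap)
      }
      for (b in seq_len(nrow(bands))) {
        bnd <- c(bands$f_low[b], bands$f_high[b])
        pw <- band_power_multi(st, bnd)
        if ("frequency" %in% families) {
          bins <- band_bins(est$freq, bnd)
          vals[e, feature_id("frequency", "psd", bands$band[b], labs)] <-
            colMeans(est$psd[bins, , drop = FALSE])
          vals[e, feature_id("frequency", "power", bands$band[b], labs)] <- pw
        }
        if ("timefreq" %in% families) {
          vals[e, feature_id("timefreq", "de", bands$band[b], labs)] <-
            ifelse(pw > 0, log(pw), NA_real_)
        }
      }
    }
    if ("network" %in% families && length(networks)) {
      for (b in seq_len(nrow(bands))) {
        bnd <- c(bands$f_low[b], bands$f_high[b])
        for (meth in networks) {
          W <- switch(meth,
            pearson = pearson_network(m, eps$fs, bnd, bands$band[b], labs),
            coherence = coherence_network(m, eps$fs, bnd, bands$band[b], labs,
                                          window_s = welch_window_s,
                                          overlap = spectral_overlap),
            plv = plv_network(m, eps$fs, bnd, bands$band[b], labs))
          gp <- graph_properties(W)
          vals[e, feature_id("network", paste0(meth, "_cc"), bands$band[b], "global")] <- gp$cc_mean
          vals[e, feature_id("network", paste0(meth, "_cpl"), bands$band[b], "global")] <- gp$cpl
          vals[e, feature_id("network", paste0(meth, "_le"), bands$band[b], "global")] <- gp$le_mean
          vals[e, feature_id("network", paste0(meth, "_ge"), bands$band[b], "global")] <- gp$ge
        }
      }
    }
  }

  fm <- new_feature_matrix(vals[, base_reg$id, drop = FALSE], base_reg,
                           eps$labels, eps$subject_id)
  if (any(c("DA", "RA") %in% families) && nrow(eps$montage$symmetric_pairs)) {
    fm <- add_asymmetry_features(fm, eps$montage,
                                 which = intersect(c("DA", "RA"), families))
  }
  fm
}

new_feature_matrix <- function(vals, meta, labels, subject_id) {
  out <- tibble::as_tibble(vals)
  attr(out, "column_meta") <- meta
  attr(out, "labels") <- labels
  attr(out, "subject_id") <- subject_id
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Column metadata and labels of a feature matrix
#'
#' @param fm A `feature_matrix` from [extract_features()].
#' @return `column_meta()` returns the registry tibble (one row per
#'   column); `epoch_labels()` the per-epoch class labels.
#' @export
column_meta <- function(fm) attr(fm, "column_meta")

#' @rdname column_meta
#' @export
epoch_labels <- function(fm) attr(fm, "labels")

#' Write a feature matrix as CSV
#'
#' One header row of column-meta identifiers
#' (`family|feature|band|electrode`), a `label` column first.
#'
#' @param fm A `feature_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(label = epoch_labels(fm), as.data.frame(fm),
                   check.names = FALSE)
  names(df) <- c("label", column_meta(fm)$id)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
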