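# Feature bookkeeping: a registry row per feature column, uniquely
# identified by (family, feature, band, electrode). Families:
#   time      - per-electrode time-domain scalars (8 features)
#   frequency - Welch band PSD and STFT band power, per band x electrode
#   timefreq  - differential entropy, per band x electrode
#   network   - method x graph property x band, one global scalar each
#   DA / RA   - differential / rational asymmetry of a per-electrode base
#               feature over the montage's symmetric pairs

TIME_FEATURES <- c("std", "fir_dif", "n_fir_dif", "sec_dif", "n_sec_dif",
                   "fd", "apen", "samen")
GRAPH_PROPS <- c("cc", "cpl", "le", "ge")

feature_id <- function(family, feature, band, electrode) {
  paste(family, feature, ifelse(is.na(band), "-", band), electrode, sep = "|")
}

#' Enumerate the feature columns of a pipeline configuration
#'
#' Deterministically lists every feature column the extraction pipeline
#' produces for a given montage, band scheme and set of enabled feature
#' families: 8 time-domain features per electrode; band PSD and band power
#' per band per electrode; differential entropy per band per electrode;
#' four graph properties per connectivity method per band; and DA/RA
#' asymmetry columns for every per-electrode base feature over the
#' montage's symmetric pairs. The enumeration is a pure function of its
#' arguments: repeated calls give identical tables.
#'
#' @param montage A [montage].
#' @param bands A [band_scheme].
#' @param families Subset of
#'   `c("time", "frequency", "timefreq", "network", "DA", "RA")`.
#' @param networks Connectivity methods to enumerate for the network
#'   family (subset of `c("pearson", "coherence", "plv")`).
#' @return A tibble with columns `family`, `feature`, `band`, `electrode`,
#'   `id`.
#' @examples
#' reg <- feature_registry(montage_preset("deap"), band_scheme_preset("deap4"),
#'                         families = "time")
#' nrow(reg)  # 8 features x 32 electrodes
#' @export
feature_registry <- function(montage, bands,
                             families = c("time", "frequency", "timefreq",
                                          "network", "DA", "RA"),
                             networks = c("pearson", "coherence", "plv")) {
  stopifnot(inherits(montage, "montage"), inherits(bands, "band_scheme"))
  families <- match.arg(families, several.ok = TRUE)
  labs <- montage$channel_labels
  rows <- list()
  add <- function(family, feature, band, electrode) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      family = family, feature = feature, band = band, electrode = electrode)
  }
  if ("time" %in% families) {
    add("time", rep(TIME_FEATURES, each = length(labs)), NA_character_,
        rep(labs, times = length(TIME_FEATURES)))
  }
  if ("frequency" %in% families) {
    for (feat in c("psd", "power")) {
      add("frequency", feat,
          rep(bands$band, each = length(labs)),
          rep(labs, times = nrow(bands)))
    }
  }
  if ("timefreq" %in% families) {
    add("timefreq", "de", rep(bands$band, each = length(labs)),
        rep(labs, times = nrow(bands)))
  }
  if ("network" %in% families && length(networks)) {
    networks <- match.arg(networks, several.ok = TRUE)
    for (meth in networks) {
      for (prop in GRAPH_PROPS) {
        add("network", paste(meth, prop, sep = "_"), bands$band, "global")
      }
    }
  }
  base <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(family = character(0), feature = character(0),
                   band = character(0), electrode = character(0))
  asym <- list()
  if (any(c("DA", "RA") %in% families) && nrow(montage$symmetric_pairs)) {
    per_el <- base[base$family %in% c("time", "frequency", "timefreq"), ]
    base_feats <- dplyr::distinct(per_el[, c("family", "feature", "band")])
    pairs <- paste(montage$symmetric_pairs[, 1], montage$symmetric_pairs[, 2], sep = "-")
    for (fam in intersect(c("DA", "RA"), families)) {
      for (r in seq_len(nrow(base_feats))) {
        asym[[length(asym) + 1]] <- tibble::tibble(
          family = fam,
          feature = paste(base_feats$family[r], base_feats$feature[r], sep = "."),
          band = base_feats$band[r],
          electrode = pairs)
      }
    }
  }
  out <- dplyr::bind_rows(c(list(base), asym))
  out$id <- feature_id(out$family, out$feature, out$band, out$electrode)
  if (anyDuplicated(out$id)) stop("feature_registry: duplicate feature ids")
  out
}
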