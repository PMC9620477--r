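#' Electrode montages
#'
#' A montage records the ordered 10-20/10-10 channel labels of a recording
#' system, the homologous left/right electrode pairs used for spatial
#' asymmetry features, and a coarse scalp-region map (frontal, temporal,
#' central, parietal, occipital).
#'
#' Two presets ship with the package:
#' * `"esd"` — a 62-channel 10-10 layout (27 homologous pairs + 8 midline
#'   electrodes) matching a 64-channel amplifier with ground and reference
#'   electrodes removed, sampled at 600 Hz in the emotional-picture study
#'   design this package emulates.
#' * `"deap"` — the standard 32-channel DEAP layout; 14 geometrically valid
#'   homologous pairs (the montage admits no more; the pair list is
#'   overridable via `symmetric_pairs`).
#'
#' @param channel_labels Character vector of unique channel labels.
#' @param symmetric_pairs Two-column character matrix (left, right); every
#'   label must occur in `channel_labels` and in at most one pair.
#' @param region_map Named character vector mapping every label to one of
#'   `"frontal"`, `"temporal"`, `"central"`, `"parietal"`, `"occipital"`.
#' @return A `montage` object (list with `channel_labels`,
#'   `symmetric_pairs`, `region_map`).
#' @examples
#' m <- montage_preset("esd")
#' length(m$channel_labels)  # 62
#' nrow(m$symmetric_pairs)   # 27
#' @export
montage <- function(channel_labels, symmetric_pairs, region_map) {
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels)) {
    stop("montage: duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  }
  symmetric_pairs <- as.matrix(symmetric_pairs)
  if (ncol(symmetric_pairs) != 2) stop("montage: symmetric_pairs must have 2 columns")
  members <- as.vector(symmetric_pairs)
  if (!all(members %in% channel_labels)) {
    stop("montage: pair members not in channel_labels: ",
         paste(setdiff(members, channel_labels), collapse = ", "))
  }
  if (anyDuplicated(members)) {
    stop("montage: a label appears in more than one symmetric pair")
  }
  region_map <- region_map[channel_labels]
  if (any(is.na(region_map))) stop("montage: region_map must cover every channel")
  ok <- c("frontal", "temporal", "central", "parietal", "occipital")
  if (!all(region_map %in% ok)) stop("montage: unknown region name")
  structure(
    list(channel_labels = channel_labels,
         symmetric_pairs = symmetric_pairs,
         region_map = region_map),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_labels), " channels, ",
      nrow(x$symmetric_pairs), " symmetric pairs\n", sep = "")
  invisible(x)
}

region_from_label <- function(labels) {
  # leading letters of a 10-20 label encode the scalp region
  stem <- sub("^([A-Za-z]+).*$", "\\1", labels)
  out <- rep(NA_character_, length(labels))
  out[stem %in% c("Fp", "Fpz", "AF", "AFz", "F", "Fz")] <- "frontal"
  out[stem %in% c("FC", "FCz", "C", "Cz", "CP", "CPz")] <- "central"
  out[stem %in% c("FT", "T", "TP")] <- "temporal"
  out[stem %in% c("P", "Pz")] <- "parietal"
  out[stem %in% c("PO", "POz", "O", "Oz", "Iz", "I")] <- "occipital"
  names(out) <- labels
  out
}

esd_pairs <- function() {
  rbind(
    c("Fp1", "Fp2"), c("AF7", "AF8"), c("AF3", "AF4"),
    c("F7", "F8"), c("F5", "F6"), c("F3", "F4"), c("F1", "F2"),
    c("FT7", "FT8"), c("FC5", "FC6"), c("FC3", "FC4"), c("FC1", "FC2"),
    c("T7", "T8"), c("C5", "C6"), c("C3", "C4"), c("C1", "C2"),
    c("TP7", "TP8"), c("CP5", "CP6"), c("CP3", "CP4"), c("CP1", "CP2"),
    c("P7", "P8"), c("P5", "P6"), c("P3", "P4"), c("P1", "P2"),
    c("PO7", "PO8"), c("PO5", "PO6"), c("PO3", "PO4"), c("O1", "O2")
  )
}

deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
    "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}

deap_pairs <- function() {
  rbind(
    c("Fp1", "Fp2"), c("AF3", "AF4"), c("F3", "F4"), c("F7", "F8"),
    c("FC5", "FC6"), c("FC1", "FC2"), c("C3", "C4"), c("T7", "T8"),
    c("CP5", "CP6"), c("CP1", "CP2"), c("P3", "P4"), c("P7", "P8"),
    c("PO3", "PO4"), c("O1", "O2")
  )
}

#' @rdname montage
#' @param preset `"esd"` or `"deap"`.
#' @export
montage_preset <- function(preset = c("esd", "deap"),
                           symmetric_pairs = NULL) {
  preset <- match.arg(preset)
  if (preset == "esd") {
    pairs <- esd_pairs()
    midline <- c("Fpz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz", "Iz")
    labels <- c(as.vector(t(pairs)), midline)
    # keep a scalp-ordered listing: front to back by pair order, midline last
  } else {
    labels <- deap_channels()
    pairs <- deap_pairs()
  }
  if (!is.null(symmetric_pairs)) pairs <- as.matrix(symmetric_pairs)
  montage(labels, pairs, region_from_label(labels))
}

#' Frequency-band schemes
#'
#' Named frequency bands used for band power, power spectral density,
#' differential entropy and band-specific connectivity. Two presets:
#' * `"esd6"`: delta (1-4), theta (4-8), alpha (8-13), beta (13-30),
#'   gamma (30-50), high_gamma (50-80) Hz.
#' * `"deap4"`: theta, alpha, beta, gamma (the 128 Hz DEAP sampling rate
#'   leaves no room above 50 Hz).
#'
#' @param bands A data frame with columns `band`, `f_low`, `f_high` (Hz).
#' @return A tibble of class `band_scheme`.
#' @examples
#' band_scheme_preset("esd6")
#' @export
band_scheme <- function(bands) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("band", "f_low", "f_high") %in% names(bands)))
  if (any(bands$f_low >= bands$f_high)) stop("band_scheme: degenerate band (f_low >= f_high)")
  if (anyDuplicated(bands$band)) stop("band_scheme: duplicate band names")
  class(bands) <- c("band_scheme", class(bands))
  bands
}

#' @rdname band_scheme
#' @param preset `"esd6"` or `"deap4"`.
#' @export
band_scheme_preset <- function(preset = c("esd6", "deap4")) {
  preset <- match.arg(preset)
  full <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma", "high_gamma"),
    f_low = c(1, 4, 8, 13, 30, 50),
    f_high = c(4, 8, 13, 30, 50, 80)
  )
  if (preset == "deap4") full <- full[full$band %in% c("theta", "alpha", "beta", "gamma"), ]
  band_scheme(full)
}
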