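# European Data Format (EDF): 256-byte ASCII main header, 256 bytes of
# ASCII signal headers per channel, then data records of 16-bit
# little-endian integers, one contiguous block per signal per record.
# Physical values are recovered by linear scaling from the digital range.

edf_field <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  trimws(raw)
}

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > n) stop("edf: field too long: ", x)
  formatC(x, width = -n, flag = " ")
}

#' Read an EDF recording
#'
#' Reads a European-Data-Format file into a single-epoch [epoch_set]
#' spanning the whole recording. Channel labels come from the EDF signal
#' headers; segmentation into stimulus-locked epochs is done downstream
#' (see [segment_epochs()]). All signals must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @param montage Optional [montage]; by default one is built from the EDF
#'   channel labels with no symmetric pairs (supply a preset to enable
#'   asymmetry features).
#' @return An `epoch_set` with one epoch and label `"recording"`.
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop("read_edf: malformed header: unsupported version field '", version, "'")
  edf_field(con, 80)  # patient
  edf_field(con, 80)  # recording
  edf_field(con, 8)   # start date
  edf_field(con, 8)   # start time
  header_bytes <- suppressWarnings(as.integer(edf_field(con, 8)))
  if (is.na(header_bytes)) stop("read_edf: malformed header: header-bytes field not numeric")
  edf_field(con, 44)  # reserved
  n_records <- suppressWarnings(as.integer(edf_field(con, 8)))
  record_dur <- suppressWarnings(as.numeric(edf_field(con, 8)))
  ns <- suppressWarnings(as.integer(edf_field(con, 4)))
  if (is.na(n_records) || is.na(record_dur) || is.na(ns) || ns < 1) {
    stop("read_edf: malformed header: record-count/duration/signal-count fields")
  }
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), character(1))
  if (anyDuplicated(labels)) stop("read_edf: duplicate channel labels in EDF header")
  for (i in seq_len(ns)) edf_field(con, 80)  # transducer
  for (i in seq_len(ns)) edf_field(con, 8)   # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), numeric(1))
  for (i in seq_len(ns)) edf_field(con, 80)  # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(edf_field(con, 8)), integer(1))
  for (i in seq_len(ns)) edf_field(con, 32)  # reserved
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr)))) {
    stop("read_edf: malformed header: signal scaling fields not numeric")
  }
  if (length(unique(spr)) != 1) {
    stop("read_edf: mixed sampling rates across signals are not supported")
  }
  fs <- spr[1] / record_dur
  n_total <- n_records * spr[1]
  mat <- matrix(0, nrow = ns, ncol = n_total)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[s], size = 2, endian = "little")
      if (length(dig) < spr[s]) stop("read_edf: truncated data record ", r)
      idx <- ((r - 1) * spr[s] + 1):(r * spr[s])
      mat[s, idx] <- (dig - dig_min[s]) * scale[s] + phys_min[s]
    }
  }
  if (is.null(montage)) {
    montage <- montage(labels, matrix(character(0), 0, 2),
                       stats::setNames(rep("central", ns), labels))
  }
  arr <- array(0, c(1, ns, n_total))
  arr[1, , ] <- mat
  epoch_set(arr, fs = fs, montage = montage, labels = "recording",
            subject_id = basename(path))
}

#' Write an epoch_set to an EDF file
#'
#' Epochs are concatenated into one continuous recording, one data record
#' per epoch. EDF stores 16-bit integers, so values are quantized to the
#' per-channel physical range (relative error ~3e-5 of the range).
#'
#' @param eps An [epoch_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eps, path) {
  stopifnot(inherits(eps, "epoch_set"))
  ns <- n_channels(eps)
  spr <- n_samples(eps)
  n_records <- n_epochs(eps)
  record_dur <- spr / eps$fs
  rng <- apply(eps$data, 2, function(v) range(v))
  phys_min <- pmin(rng[1, ], -1)
  phys_max <- pmax(rng[2, ], 1)
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic", 80), edf_pad("eegvalence", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_records, 8), edf_pad(format(record_dur, digits = 7), 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(vapply(vals, edf_pad, "", n = w), collapse = ""), con, eos = NULL)
  fld(eps$montage$channel_labels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(phys_min, digits = 6, format = "g"), 8)
  fld(formatC(phys_max, digits = 6, format = "g"), 8)
  fld(rep(dig_min, ns), 8)
  fld(rep(dig_max, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(spr, ns), 8)
  fld(rep("", ns), 32)
  pm <- as.numeric(formatC(phys_min, digits = 6, format = "g"))
  px <- as.numeric(formatC(phys_max, digits = 6, format = "g"))
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      v <- eps$data[r, s, ]
      dig <- round((v - pm[s]) / (px[s] - pm[s]) * (dig_max - dig_min) + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
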