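# Internal container: <path>.bin holds the epoch array as little-endian
# float64 in epoch-major order; <path>.json is a sidecar with shape, fs,
# montage, labels, ratings and a format version. Lossless at double
# precision, unlike EDF's 16-bit quantization.

CONTAINER_VERSION <- 1L

#' Save / load the internal epoch container
#'
#' `save_container()` writes an [epoch_set] as a raw float64 matrix file
#' (`<path>.bin`) plus a JSON sidecar (`<path>.json`) carrying shape,
#' sampling rate, montage, labels and optional ratings. `load_container()`
#' restores it losslessly.
#'
#' @param eps An [epoch_set].
#' @param path Path prefix (without extension).
#' @return `save_container()` returns `path` invisibly; `load_container()`
#'   returns the restored `epoch_set`.
#' @examples
#' es <- generate_subject(generator_spec(preset = "esd", n_trials_per_class = 1,
#'                                       epoch_length = 0.1), 1)
#' p <- file.path(tempdir(), "demo")
#' save_container(es, p)
#' identical(load_container(p)$data, es$data)
#' @export
save_container <- function(eps, path) {
  stopifnot(inherits(eps, "epoch_set"))
  meta <- list(
    version = CONTAINER_VERSION,
    shape = dim(eps$data),
    dtype = "float64le",
    fs = eps$fs,
    subject_id = eps$subject_id,
    channel_labels = eps$montage$channel_labels,
    symmetric_pairs = apply(eps$montage$symmetric_pairs, 1, identity, simplify = FALSE),
    region_map = as.list(eps$montage$region_map),
    labels = eps$labels,
    ratings = if (is.null(eps$ratings)) NULL else
      list(valence = eps$ratings$valence, arousal = eps$ratings$arousal)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(eps$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  jpath <- paste0(path, ".json"); bpath <- paste0(path, ".bin")
  if (!file.exists(jpath) || !file.exists(bpath)) {
    stop("load_container: missing ", if (!file.exists(jpath)) jpath else bpath)
  }
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  if (is.null(meta$version) || meta$version != CONTAINER_VERSION) {
    stop("load_container: container format version ",
         if (is.null(meta$version)) "<missing>" else meta$version,
         " does not match supported version ", CONTAINER_VERSION)
  }
  shape <- as.integer(meta$shape)
  n_vals <- prod(shape)
  expected_bytes <- n_vals * 8
  if (file.info(bpath)$size != expected_bytes) {
    stop("load_container: data file has ", file.info(bpath)$size,
         " bytes, expected ", expected_bytes, " (truncated or corrupt)")
  }
  con <- file(bpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n_vals, size = 8, endian = "little")
  pairs <- meta$symmetric_pairs
  pairs <- if (is.null(pairs) || !length(pairs)) matrix(character(0), 0, 2)
           else if (is.matrix(pairs)) pairs
           else do.call(rbind, pairs)
  m <- montage(meta$channel_labels, pairs, unlist(meta$region_map))
  ratings <- NULL
  if (!is.null(meta$ratings) && length(meta$ratings)) {
    ratings <- tibble::tibble(valence = meta$ratings$valence,
                              arousal = meta$ratings$arousal)
  }
  epoch_set(array(vals, shape), fs = as.numeric(meta$fs), montage = m,
            labels = as.character(meta$labels), ratings = ratings,
            subject_id = meta$subject_id)
}
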