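#' Per-feature computing-time table
#'
#' Times each feature family on a single epoch (default shape: 62
#' channels x 1200 samples at 600 Hz, i.e. one 2 s trial) and reports the
#' median wall-clock seconds over `reps` repetitions, plus a rank column
#' as a hardware-independent relative ordering. Absolute times depend on
#' the machine; only the ordering is meaningful across systems.
#'
#' @param eps An [epoch_set]; its first epoch is timed.
#' @param features Which feature computations to time (default: the eight
#'   time-domain features, the three spectral features, and the three
#'   connectivity networks each followed by the four graph properties).
#' @param reps Repetitions per feature (median reported; default 5).
#' @param band Band used for spectral/network timing (Hz).
#' @return A tibble `feature`, `median_s`, `reps`, `rank` sorted by the
#'   timed ordering.
#' @export
timing_table <- function(eps,
                         features = c("std", "fir_dif", "n_fir_dif",
                                      "sec_dif", "n_sec_dif", "fd", "apen",
                                      "samen", "psd", "power", "de",
                                      "pearson_net", "plv_net",
                                      "coherence_net"),
                         reps = 5, band = c(30, 50)) {
  stopifnot(inherits(eps, "epoch_set"))
  m <- epoch_matrix(eps, 1)
  fs <- eps$fs
  per_channel <- function(f) for (ch in seq_len(nrow(m))) f(m[ch, ])
  runners <- list(
    std = function() per_channel(feat_std),
    fir_dif = function() per_channel(first_diff),
    n_fir_dif = function() per_channel(norm_first_diff),
    sec_dif = function() per_channel(second_diff),
    n_sec_dif = function() per_channel(norm_second_diff),
    fd = function() per_channel(function(x) higuchi_fd(x)),
    apen = function() per_channel(function(x) approx_entropy(x)),
    samen = function() per_channel(function(x) sample_entropy(x)),
    psd = function() per_channel(function(x) band_psd(x, fs, band)),
    power = function() per_channel(function(x) band_power(x, fs, band)),
    de = function() per_channel(function(x) differential_entropy(x, fs, band)),
    pearson_net = function() graph_properties(pearson_network(m, fs, band)),
    plv_net = function() graph_properties(plv_network(m, fs, band)),
    coherence_net = function() graph_properties(coherence_network(m, fs, band))
  )
  features <- match.arg(features, names(runners), several.ok = TRUE)
  out <- lapply(features, function(f) {
    times <- vapply(seq_len(reps), function(i) {
      system.time(runners[[f]]())[["elapsed"]]
    }, numeric(1))
    tibble::tibble(feature = f, median_s = median(times), reps = reps)
  })
  out <- dplyr::bind_rows(out)
  out$rank <- rank(out$median_s, ties.method = "first")
  out
}
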