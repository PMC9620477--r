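# Preprocessing chain: band-pass filter -> average reference -> baseline
# correction -> (optional) segmentation. All operations preserve epoch
# order and labels.

# Zero-phase Butterworth band-pass. The 0.1 Hz lower corner sits at a
# normalized frequency of ~3e-4 where high-order IIR designs are
# numerically unstable, so the band-pass is realized as a gentle
# (order-2) high-pass cascaded with a steep (order-8) low-pass, each
# applied forward-backward.
bandpass_vector <- function(x, f_low, f_high, fs, hp_order = 2, lp_order = 8) {
  if (f_low > 0) {
    hp <- signal::butter(hp_order, f_low / (fs / 2), type = "high")
    x <- signal::filtfilt(hp, x)
  }
  lp <- signal::butter(lp_order, f_high / (fs / 2), type = "low")
  signal::filtfilt(lp, x)
}

#' Band-pass filter all epochs
#'
#' Applies a zero-phase Butterworth band-pass per channel per epoch
#' (order-2 high-pass at `f_low`, order-8 low-pass at `f_high`,
#' forward-backward). Shape, labels and metadata are preserved.
#'
#' @param eps An [epoch_set].
#' @param f_low,f_high Corner frequencies in Hz; `f_high` must be below
#'   the Nyquist frequency.
#' @return A filtered `epoch_set`.
#' @export
bandpass_filter <- function(eps, f_low = 0.1, f_high = 80) {
  stopifnot(inherits(eps, "epoch_set"))
  if (f_high >= eps$fs / 2) {
    stop("bandpass_filter: f_high (", f_high, " Hz) must be below Nyquist (",
         eps$fs / 2, " Hz)")
  }
  if (f_low < 0 || f_low >= f_high) stop("bandpass_filter: need 0 <= f_low < f_high")
  out <- eps
  for (e in seq_len(n_epochs(eps))) {
    for (ch in seq_len(n_channels(eps))) {
      out$data[e, ch, ] <- bandpass_vector(eps$data[e, ch, ], f_low, f_high, eps$fs)
    }
  }
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel,
#' so the cross-channel mean is zero at every sample.
#'
#' @param eps An [epoch_set] with at least two channels.
#' @return A re-referenced `epoch_set`.
#' @export
average_reference <- function(eps) {
  stopifnot(inherits(eps, "epoch_set"))
  if (n_channels(eps) < 2) stop("average_reference: needs >= 2 channels")
  out <- eps
  for (e in seq_len(n_epochs(eps))) {
    m <- epoch_matrix(eps, e)
    out$data[e, , ] <- sweep(m, 2, colMeans(m))
  }
  out
}

#' Baseline-correct epochs
#'
#' For each epoch and channel, subtracts the mean of the baseline window
#' (the first `baseline_s` seconds of the stored samples) from the rest of
#' the epoch, then drops the baseline samples.
#'
#' @param eps An [epoch_set] whose epochs begin with the baseline period.
#' @param baseline_s Baseline duration in seconds (must be shorter than
#'   the epoch).
#' @return An `epoch_set` containing only the analysis window.
#' @export
baseline_correct <- function(eps, baseline_s) {
  stopifnot(inherits(eps, "epoch_set"))
  nb <- round(baseline_s * eps$fs)
  if (nb < 1 || nb >= n_samples(eps)) {
    stop("baseline_correct: baseline window (", nb, " samples) outside epoch of ",
         n_samples(eps), " samples")
  }
  keep <- (nb + 1):n_samples(eps)
  arr <- array(0, c(n_epochs(eps), n_channels(eps), length(keep)))
  for (e in seq_len(n_epochs(eps))) {
    m <- epoch_matrix(eps, e)
    base_mean <- rowMeans(m[, seq_len(nb), drop = FALSE])
    arr[e, , ] <- m[, keep, drop = FALSE] - base_mean
  }
  epoch_set(arr, eps$fs, eps$montage, eps$labels,
            ratings = eps$ratings, subject_id = eps$subject_id)
}

#' Keep only the last seconds of every epoch
#'
#' Used for long stimulus trials where the emotional response builds up
#' over time and only the late portion is analyzed.
#'
#' @param eps An [epoch_set].
#' @param seconds Duration to keep from the end of each epoch.
#' @return A trimmed `epoch_set`.
#' @export
keep_last <- function(eps, seconds) {
  stopifnot(inherits(eps, "epoch_set"))
  n <- round(seconds * eps$fs)
  if (n > n_samples(eps)) stop("keep_last: requested window longer than epoch")
  keep <- (n_samples(eps) - n + 1):n_samples(eps)
  epoch_set(eps$data[, , keep, drop = FALSE], eps$fs, eps$montage, eps$labels,
            ratings = eps$ratings, subject_id = eps$subject_id)
}

#' Segment epochs into fixed-length sub-epochs
#'
#' Each epoch is replaced by consecutive windows of `window_s` seconds
#' advancing by `window_s - overlap_s`; every sub-epoch inherits the
#' parent epoch's label (and ratings).
#'
#' @param eps An [epoch_set].
#' @param window_s Window length in seconds (at most the epoch length).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (0 = non-overlapping).
#' @return An `epoch_set` of sub-epochs.
#' @export
segment_epochs <- function(eps, window_s, overlap_s = 0) {
  stopifnot(inherits(eps, "epoch_set"))
  win <- round(window_s * eps$fs)
  hop <- round((window_s - overlap_s) * eps$fs)
  if (win > n_samples(eps)) stop("segment_epochs: window longer than epoch")
  if (hop < 1) stop("segment_epochs: overlap must be smaller than the window")
  starts <- seq(1, n_samples(eps) - win + 1, by = hop)
  n_sub <- length(starts)
  arr <- array(0, c(n_epochs(eps) * n_sub, n_channels(eps), win))
  labels <- character(n_epochs(eps) * n_sub)
  rat_idx <- integer(n_epochs(eps) * n_sub)
  k <- 0
  for (e in seq_len(n_epochs(eps))) {
    for (s in starts) {
      k <- k + 1
      arr[k, , ] <- eps$data[e, , s:(s + win - 1)]
      labels[k] <- eps$labels[e]
      rat_idx[k] <- e
    }
  }
  epoch_set(arr, eps$fs, eps$montage, labels,
            ratings = if (is.null(eps$ratings)) NULL else eps$ratings[rat_idx, , drop = FALSE],
            subject_id = eps$subject_id)
}

#' Remove ocular artifacts (extension hook)
#'
#' Placeholder for blind-source-separation EOG removal. Component-based
#' artifact rejection needs human inspection of the unmixed sources and
#' real ocular activity; synthetic data contains neither, so the default
#' implementation is the identity. Supply `fun` to plug in a real cleaner.
#'
#' @param eps An [epoch_set].
#' @param fun Optional function `epoch_set -> epoch_set`.
#' @return An `epoch_set`.
#' @export
remove_eog <- function(eps, fun = NULL) {
  stopifnot(inherits(eps, "epoch_set"))
  if (is.null(fun)) eps else fun(eps)
}
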