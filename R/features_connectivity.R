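# Band-specific electrode-by-electrode connectivity. Pearson and PLV are
# computed on band-limited signals (ideal FFT band-limiter; exactly zero
# response outside the band, no phase distortion). Coherence is computed
# from Welch auto/cross spectra and averaged over the band's frequency
# bins, which is band-specific by construction.

# Ideal band-limiter: zero all FFT bins outside [f_low, f_high].
band_limit <- function(x, fs, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  X <- fft(x)
  X[f < band[1] | f > band[2]] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

# Analytic signal via FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

new_connectivity_matrix <- function(W, labels, method, band_name) {
  dimnames(W) <- list(labels, labels)
  diag(W) <- 0
  W <- (W + t(W)) / 2  # enforce exact symmetry against fp asymmetry
  structure(list(W = W, method = method, band_name = band_name),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", x$method, " / ", x$band_name, ", ",
      nrow(x$W), " nodes\n", sep = "")
  invisible(x)
}

#' Connectivity networks from one epoch
#'
#' Build a symmetric electrode-by-electrode network from one epoch's
#' `channels x samples` matrix:
#' * `pearson_network()` — pairwise Pearson correlation of the
#'   band-limited signals (entries in `[-1, 1]`; zero-variance channels
#'   get zero rows with a warning).
#' * `coherence_network()` — magnitude-squared coherence
#'   `|Pxy|^2 / (Pxx Pyy)` from Welch spectra, averaged over the band's
#'   frequency bins (entries in `[0, 1]`).
#' * `plv_network()` — phase-locking value: modulus of the time-averaged
#'   unit phasor of the instantaneous (analytic-signal) phase difference
#'   of the band-limited signals (entries in `[0, 1]`).
#'
#' Diagonals are zero by convention.
#'
#' @param m Numeric matrix `channels x samples` (one epoch).
#' @param fs Sampling rate in Hz.
#' @param band Numeric `c(f_low, f_high)` in Hz.
#' @param band_name Label stored on the result.
#' @param labels Channel labels (default row names or `ch1..chN`).
#' @param window_s,overlap Welch settings for `coherence_network()`.
#' @return A `connectivity_matrix` (fields `W`, `method`, `band_name`).
#' @name connectivity
NULL

node_labels <- function(m, labels) {
  if (!is.null(labels)) labels
  else if (!is.null(rownames(m))) rownames(m)
  else paste0("ch", seq_len(nrow(m)))
}

#' @rdname connectivity
#' @export
pearson_network <- function(m, fs = NULL, band = NULL, band_name = "broadband",
                            labels = NULL) {
  if (nrow(m) < 2) stop("pearson_network: needs >= 2 channels")
  labs <- node_labels(m, labels)
  if (!is.null(band)) {
    check_band(band, fs)
    m <- t(apply(m, 1, band_limit, fs = fs, band = band))
  }
  sds <- apply(m, 1, sd)
  W <- matrix(0, nrow(m), nrow(m))
  ok <- sds > 0
  if (any(!ok)) warning("pearson_network: zero-variance channel(s) ",
                        paste(labs[!ok], collapse = ", "), "; rows zeroed")
  if (sum(ok) >= 2) W[ok, ok] <- cor(t(m[ok, , drop = FALSE]))
  new_connectivity_matrix(W, labs, "pearson", band_name)
}

#' @rdname connectivity
#' @export
coherence_network <- function(m, fs, band, band_name = "broadband",
                              labels = NULL, window_s = 1, overlap = 0.5) {
  if (nrow(m) < 2) stop("coherence_network: needs >= 2 channels")
  check_band(band, fs)
  labs <- node_labels(m, labels)
  n <- ncol(m)
  win <- min(round(window_s * fs), n)
  hop <- max(1L, round(win * (1 - overlap)))
  w <- hamming_win(win)
  starts <- frame_starts(n, win, hop)
  if (length(starts) < 2) {
    warning("coherence_network: a single Welch segment makes coherence ",
            "identically 1; shorten window_s or lengthen the epoch")
  }
  nfreq <- win %/% 2 + 1
  freq <- (seq_len(nfreq) - 1) * fs / win
  bins <- band_bins(freq, band)
  nch <- nrow(m)
  # windowed FFTs: [channel x freq x segment]
  Xs <- array(complex(real = 0), c(nch, length(bins), length(starts)))
  for (j in seq_along(starts)) {
    seg <- m[, starts[j]:(starts[j] + win - 1), drop = FALSE]
    seg <- sweep(seg, 2, w, `*`)
    for (ch in seq_len(nch)) {
      Xs[ch, , j] <- fft(seg[ch, ])[bins]
    }
  }
  Pauto <- apply(Mod(Xs)^2, c(1, 2), mean)
  W <- matrix(0, nch, nch)
  for (a in seq_len(nch - 1)) {
    for (b in (a + 1):nch) {
      Pxy <- rowMeans(matrix(Xs[a, , ] * Conj(Xs[b, , ]), nrow = length(bins)))
      denom <- Pauto[a, ] * Pauto[b, ]
      good <- denom > 0
      if (!any(good)) next
      W[a, b] <- mean(Mod(Pxy[good])^2 / denom[good])
    }
  }
  if (any(apply(m, 1, sd) == 0)) warning("coherence_network: zero-variance channel(s); rows zeroed")
  new_connectivity_matrix(W + t(W), labs, "coherence", band_name)
}

#' @rdname connectivity
#' @export
plv_network <- function(m, fs, band, band_name = "broadband", labels = NULL) {
  if (nrow(m) < 2) stop("plv_network: needs >= 2 channels")
  check_band(band, fs)
  labs <- node_labels(m, labels)
  nch <- nrow(m)
  phases <- matrix(0, nch, ncol(m))
  for (ch in seq_len(nch)) {
    z <- analytic_signal(band_limit(m[ch, ], fs, band))
    phases[ch, ] <- Arg(z)
  }
  W <- matrix(0, nch, nch)
  for (a in seq_len(nch - 1)) {
    for (b in (a + 1):nch) {
      dphi <- phases[a, ] - phases[b, ]
      W[a, b] <- Mod(mean(exp(1i * dphi)))
    }
  }
  new_connectivity_matrix(W + t(W), labs, "plv", band_name)
}
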