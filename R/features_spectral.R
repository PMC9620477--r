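# Spectral features: Welch band power spectral density, short-time-Fourier
# band power, and differential entropy (natural log of STFT band power).
# Defaults: Welch = 1 s Hamming windows with 50% overlap; STFT = 0.5 s
# Hamming with 50% overlap (2 s epochs then yield 7 frames). Band edges
# are inclusive on both sides, so a shared edge (8 Hz in theta and alpha)
# contributes to both bands, matching the band table convention.

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

frame_starts <- function(n, win, hop) {
  if (win > n) return(1L)
  seq(1L, n - win + 1L, by = hop)
}

# Welch one-sided PSD estimate: list(freq, psd) in units of uV^2/Hz
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  n <- length(x)
  win <- min(round(window_s * fs), n)
  hop <- max(1L, round(win * (1 - overlap)))
  w <- hamming_win(win)
  U <- sum(w^2)
  starts <- frame_starts(n, win, hop)
  nfreq <- win %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + win - 1)] * w
    X <- fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double the interior bins
  if (nfreq > 2) psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  list(freq = (seq_len(nfreq) - 1) * fs / win, psd = psd)
}

# STFT magnitude-squared spectrogram: matrix [freq x frame]
stft_power <- function(x, fs, window_s = 0.5, overlap = 0.5) {
  n <- length(x)
  win <- min(round(window_s * fs), n)
  hop <- max(1L, round(win * (1 - overlap)))
  w <- hamming_win(win)
  starts <- frame_starts(n, win, hop)
  nfreq <- win %/% 2 + 1
  S <- matrix(0, nfreq, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + win - 1)] * w
    S[, j] <- Mod(fft(seg)[seq_len(nfreq)])^2
  }
  list(freq = (seq_len(nfreq) - 1) * fs / win, power = S)
}

# Batched short-time spectra for all channels of one epoch: frames all
# channels into one matrix and runs a single mvfft. Returns |X|^2 as
# [nfreq x (nframes * nch)] with channel ch occupying columns
# ch, ch + nch, ch + 2 nch, ...
stft_frames_multi <- function(m, fs, window_s, overlap) {
  n <- ncol(m); nch <- nrow(m)
  win <- min(round(window_s * fs), n)
  hop <- max(1L, round(win * (1 - overlap)))
  w <- hamming_win(win)
  starts <- frame_starts(n, win, hop)
  nf <- length(starts)
  nfreq <- win %/% 2 + 1
  Fm <- matrix(0, win, nf * nch)
  for (j in seq_len(nf)) {
    seg <- t(m[, starts[j]:(starts[j] + win - 1), drop = FALSE]) * w
    Fm[, ((j - 1) * nch + 1):(j * nch)] <- seg
  }
  X <- stats::mvfft(Fm)[seq_len(nfreq), , drop = FALSE]
  list(freq = (seq_len(nfreq) - 1) * fs / win, pow = Mod(X)^2,
       nf = nf, nch = nch, U = sum(w^2))
}

# Per-channel Welch PSD matrix [nfreq x nch] from the batched frames.
welch_psd_multi <- function(m, fs, window_s = 1, overlap = 0.5) {
  st <- stft_frames_multi(m, fs, window_s, overlap)
  nfreq <- length(st$freq)
  psd <- matrix(0, nfreq, st$nch)
  for (ch in seq_len(st$nch)) {
    cols <- seq(ch, by = st$nch, length.out = st$nf)
    psd[, ch] <- rowMeans(st$pow[, cols, drop = FALSE]) / (fs * st$U)
  }
  if (nfreq > 2) psd[2:(nfreq - 1), ] <- 2 * psd[2:(nfreq - 1), ]
  list(freq = st$freq, psd = psd)
}

# Per-channel STFT band power [nch] summed over band bins and frames.
band_power_multi <- function(st, band) {
  bins <- band_bins(st$freq, band)
  vapply(seq_len(st$nch), function(ch) {
    cols <- seq(ch, by = st$nch, length.out = st$nf)
    sum(st$pow[bins, cols])
  }, numeric(1))
}

band_bins <- function(freq, band) {
  idx <- which(freq >= band[1] & freq <= band[2])
  if (!length(idx)) stop("no spectral bins inside band [", band[1], ", ", band[2], "] Hz")
  idx
}

#' Spectral features of a sample sequence
#'
#' `band_psd()` is the Welch power spectral density averaged over the bins
#' of a frequency band (uV^2/Hz). `band_power()` is the total
#' short-time-Fourier power summed over band bins and time frames (uV^2).
#' `differential_entropy()` is the natural logarithm of that band power;
#' the identity `differential_entropy(x) == log(band_power(x))` holds
#' exactly for matching settings.
#'
#' @param x Numeric sample sequence.
#' @param fs Sampling rate in Hz.
#' @param band Numeric `c(f_low, f_high)` in Hz, inside `(0, fs/2)`
#'   (band edges inclusive when binning).
#' @param window_s,overlap Analysis window length (s) and overlap
#'   fraction. Welch default 1 s / 0.5; STFT default 0.5 s / 0.5.
#' @return A scalar.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 600)[-1])
#' band_psd(x, 600, c(8, 13)) > band_psd(x, 600, c(13, 30))
#' @name spectral_features
NULL

check_band <- function(band, fs) {
  if (length(band) != 2 || band[1] >= band[2]) stop("band must be c(f_low, f_high) with f_low < f_high")
  if (band[2] > fs / 2) stop("band upper edge ", band[2], " Hz exceeds Nyquist ", fs / 2, " Hz")
}

#' @rdname spectral_features
#' @export
band_psd <- function(x, fs, band, window_s = 1, overlap = 0.5) {
  check_band(band, fs)
  est <- welch_psd(x, fs, window_s, overlap)
  mean(est$psd[band_bins(est$freq, band)])
}

#' @rdname spectral_features
#' @export
band_power <- function(x, fs, band, window_s = 0.5, overlap = 0.5) {
  check_band(band, fs)
  est <- stft_power(x, fs, window_s, overlap)
  sum(est$power[band_bins(est$freq, band), ])
}

#' @rdname spectral_features
#' @export
differential_entropy <- function(x, fs, band, window_s = 0.5, overlap = 0.5) {
  p <- band_power(x, fs, band, window_s, overlap)
  if (p <= 0) {
    warning("differential_entropy: zero band power; returning NA")
    return(NA_real_)
  }
  log(p)
}
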