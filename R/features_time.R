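# Time-domain features computed per electrode on one sample sequence.
# Conventions: population (1/N) standard deviation; mean absolute lag-1
# and lag-2 differences with the printed 1/(N-1), 1/(N-2) normalizers;
# Higuchi fractal dimension with OLS slope in log-log space; approximate
# and sample entropy with Chebyshev distance, m = 2, r = 0.2 * Std.

#' Time-domain features of a sample sequence
#'
#' Eight per-electrode time-domain features: population standard deviation
#' (`feat_std`), mean absolute first/second-order differences
#' (`first_diff`, `second_diff`) and their Std-normalized versions,
#' Higuchi fractal dimension (`higuchi_fd`), approximate entropy
#' (`approx_entropy`) and sample entropy (`sample_entropy`).
#'
#' @param x Numeric sample sequence (microvolts).
#' @return A scalar feature value.
#' @examples
#' x <- c(1, 3, 2, 5)
#' feat_std(x)       # sqrt(8.75 / 4)
#' first_diff(x)     # 2
#' second_diff(x)    # 1.5
#' @name time_features
NULL

#' @rdname time_features
#' @export
feat_std <- function(x) {
  n <- length(x)
  if (n < 2) stop("feat_std: need at least 2 samples")
  sqrt(sum((x - mean(x))^2) / n)
}

#' @rdname time_features
#' @export
first_diff <- function(x) {
  n <- length(x)
  if (n < 2) stop("first_diff: need at least 2 samples")
  sum(abs(diff(x))) / (n - 1)
}

#' @rdname time_features
#' @export
second_diff <- function(x) {
  n <- length(x)
  if (n < 3) stop("second_diff: need at least 3 samples")
  sum(abs(x[3:n] - x[1:(n - 2)])) / (n - 2)
}

#' @rdname time_features
#' @export
norm_first_diff <- function(x) {
  s <- feat_std(x)
  if (s == 0) stop("norm_first_diff: zero standard deviation")
  first_diff(x) / s
}

#' @rdname time_features
#' @export
norm_second_diff <- function(x) {
  s <- feat_std(x)
  if (s == 0) stop("norm_second_diff: zero standard deviation")
  second_diff(x) / s
}

#' @rdname time_features
#' @param k_max Maximum Higuchi sampling interval (`>= 2`,
#'   `< length(x) / 2`).
#' @details `higuchi_fd` computes normalized curve lengths `L(k)` for
#'   `k = 1..k_max` at every sampling offset, then fits the fractal
#'   dimension as minus the ordinary-least-squares slope of `log L(k)`
#'   against `log k`. Smooth curves give values near 1, white noise near 2.
#' @export
higuchi_fd <- function(x, k_max = 8) {
  n <- length(x)
  if (k_max < 2) stop("higuchi_fd: k_max must be >= 2")
  if (n <= 2 * k_max) stop("higuchi_fd: series too short for k_max = ", k_max)
  L <- higuchi_lengths_c(as.numeric(x), as.integer(k_max))
  if (any(!is.finite(L)) || any(L <= 0)) stop("higuchi_fd: degenerate curve lengths")
  k <- seq_len(k_max)
  -unname(stats::coef(stats::lm(log(L) ~ log(k)))[2])
}

#' @rdname time_features
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a multiple of the sequence's population
#'   standard deviation (default 0.2).
#' @details Entropies use the Chebyshev (maximum-coordinate) distance.
#'   `approx_entropy` includes template self-matches and returns
#'   `Phi_m(r) - Phi_{m+1}(r)` in nats; a constant sequence returns 0 by
#'   convention. `sample_entropy` excludes self-matches; if no template
#'   pair matches at dimension `m + 1` the value is undefined and `NA` is
#'   returned with a warning.
#' @export
approx_entropy <- function(x, m = 2, r_factor = 0.2) {
  if (m < 1) stop("approx_entropy: m must be >= 1")
  if (r_factor <= 0) stop("approx_entropy: r_factor must be > 0")
  s <- feat_std(x)
  if (s == 0) return(0)
  apen_c(as.numeric(x), as.integer(m), r_factor * s)
}

#' @rdname time_features
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  if (m < 1) stop("sample_entropy: m must be >= 1")
  if (r_factor <= 0) stop("sample_entropy: r_factor must be > 0")
  s <- feat_std(x)
  if (s == 0) return(0)
  v <- sampen_c(as.numeric(x), as.integer(m), r_factor * s)
  if (is.na(v)) warning("sample_entropy: no template matches at dimension m+1; returning NA")
  v
}
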