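# Independent brute-force oracles used to validate the package's
# implementations. Deliberately written as plain double loops / explicit
# all-pairs algorithms, sharing no code with the implementation paths
# they check.

# Approximate entropy: explicit template loops, Chebyshev distance,
# self-matches included.
oracle_apen <- function(x, m, r) {
  phi <- function(dim) {
    M <- length(x) - dim + 1
    templates <- sapply(seq_len(M), function(i) x[i:(i + dim - 1)])
    total <- 0
    for (i in seq_len(M)) {
      cnt <- 0
      for (j in seq_len(M)) {
        if (max(abs(templates[, i] - templates[, j])) <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / M)
    }
    total / M
  }
  phi(m) - phi(m + 1)
}

# Sample entropy: explicit loops, self-matches excluded.
oracle_sampen <- function(x, m, r) {
  count_pairs <- function(dim) {
    M <- length(x) - dim + 1
    cnt <- 0
    for (i in seq_len(M - 1)) {
      for (j in (i + 1):M) {
        if (max(abs(x[i:(i + dim - 1)] - x[j:(j + dim - 1)])) <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  a <- count_pairs(m); b <- count_pairs(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  log(a) - log(b)
}

# All-pairs shortest paths by Floyd-Warshall on a length matrix
# (Inf = absent edge).
oracle_fw <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Weighted graph properties by direct sums, matching the documented
# conventions: |w| weights, zero diagonal, max-normalized weights for
# CC/Le, edge length 1/w for paths, CPL over reachable pairs, unreachable
# pairs contribute 0 to efficiencies.
oracle_graph <- function(W) {
  W <- abs(W); diag(W) <- 0
  n <- nrow(W); mx <- max(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  d <- oracle_fw(len)
  off <- d[row(d) != col(d)]
  cpl <- mean(off[is.finite(off)])
  ge <- mean(ifelse(is.finite(off), 1 / off, 0))
  Wn <- W / mx
  cc <- numeric(n); le <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != h) acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
      }
    }
    cc[i] <- acc / (k * (k - 1))
    nb <- which(W[i, ] > 0)
    lensub <- ifelse(W[nb, nb] > 0, 1 / W[nb, nb], Inf)
    dsub <- oracle_fw(lensub) * mx  # distances on the normalized scale
    accl <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a == b) next
        invd <- if (is.finite(dsub[a, b]) && dsub[a, b] > 0) 1 / dsub[a, b] else 0
        accl <- accl + (Wn[i, nb[a]] * Wn[i, nb[b]] * invd)^(1 / 3)
      }
    }
    le[i] <- accl / (k * (k - 1))
  }
  list(cc_mean = mean(cc), cpl = cpl, le_mean = mean(le), ge = ge)
}

# Exhaustive greedy mRMR (MID): recomputes every score from scratch at
# every step through the public mutual-information estimator.
oracle_mrmr <- function(X, y, k, n_bins = 8) {
  X <- as.matrix(X)
  rel <- sapply(seq_len(ncol(X)), function(j) mutual_information(X[, j], y, n_bins))
  sel <- integer(0)
  rem <- seq_len(ncol(X))
  for (s in seq_len(k)) {
    scores <- sapply(rem, function(j) {
      if (!length(sel)) return(rel[j])
      red <- mean(sapply(sel, function(i) {
        mutual_information(X[, j], X[, i], n_bins, y_continuous = TRUE)
      }))
      rel[j] - red
    })
    pick <- rem[which.max(scores)]
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  sel
}
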