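make_tone_epochs <- function(freqs, fs = 600, dur = 5) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  arr <- array(0, c(1, length(freqs), length(t)))
  for (i in seq_along(freqs)) arr[1, i, ] <- sin(2 * pi * freqs[i] * t)
  labs <- paste0("ch", seq_along(freqs))
  epoch_set(arr, fs, montage(labs, matrix(character(0), 0, 2),
                             stats::setNames(rep("central", length(freqs)), labs)),
            labels = "x")
}

rms <- function(v) sqrt(mean(v^2))

test_that("band-pass filter preserves pass-band tones and rejects stop-band tones", {
  es <- make_tone_epochs(c(10, 100))
  out <- bandpass_filter(es, 0.1, 80)
  expect_equal(rms(out$data[1, 1, ]) / rms(es$data[1, 1, ]), 1, tolerance = 0.02)
  expect_lt(rms(out$data[1, 2, ]) / rms(es$data[1, 2, ]), 0.05)
  zero <- es; zero$data[] <- 0
  expect_equal(bandpass_filter(zero, 0.1, 80)$data, zero$data)
  expect_error(bandpass_filter(es, 0.1, 300), "Nyquist")
})

test_that("average reference zeroes the cross-channel mean and rejects common-mode offsets", {
  es <- tiny_epochs(3)
  ref <- average_reference(es)
  for (e in 1:3) {
    expect_lt(max(abs(colMeans(ref$data[e, , ]))), 1e-10)
  }
  # adding a common offset changes nothing after re-referencing
  off <- es; off$data <- off$data + 7.5
  expect_equal(average_reference(off)$data, ref$data, tolerance = 1e-12)
  # two antisymmetric channels are already average-referenced
  a <- sin(seq(0, 10, length.out = 128))
  arr <- array(0, c(1, 2, 128)); arr[1, 1, ] <- a; arr[1, 2, ] <- -a
  es2 <- epoch_set(arr, 128, montage(c("C3", "C4"), rbind(c("C3", "C4")),
                                     c(C3 = "central", C4 = "central")), "x")
  expect_equal(average_reference(es2)$data, es2$data, tolerance = 1e-12)
  es1 <- subset_channels(es, "F3")
  expect_error(average_reference(es1), ">= 2 channels")
})

test_that("baseline correction subtracts the baseline mean and drops its samples", {
  fs <- 600
  arr <- array(rnorm(1 * 2 * 1500), c(1, 2, 1500))
  arr[1, 1, 1:300] <- arr[1, 1, 1:300] - mean(arr[1, 1, 1:300]) + 7  # baseline mean 7
  labs <- c("a", "b")
  es <- epoch_set(arr, fs, montage(labs, matrix(character(0), 0, 2),
                                   stats::setNames(rep("central", 2), labs)), "x")
  out <- baseline_correct(es, 0.5)
  expect_equal(n_samples(out), 1200)  # 500 ms at 600 Hz = 300 samples removed
  expect_equal(out$data[1, 1, ], arr[1, 1, 301:1500] - 7, tolerance = 1e-12)
  # zero-mean baseline = identity on the analysis window
  expect_equal(out$data[1, 2, ], arr[1, 2, 301:1500] - mean(arr[1, 2, 1:300]),
               tolerance = 1e-12)
  expect_error(baseline_correct(es, 10), "outside")
})

test_that("segmentation yields the right window count, labels and sample identity", {
  fs <- 128
  es <- tiny_epochs(2, n_samples = 30 * fs, fs = fs, labels = c("high", "low"))
  seg <- segment_epochs(es, 5)
  expect_equal(n_epochs(seg), 2 * 6)  # 30 s / 5 s non-overlapping
  expect_equal(seg$labels, rep(c("high", "low"), each = 6))
  # window = epoch length -> identity
  one <- segment_epochs(es, 30)
  expect_equal(one$data, es$data)
  # keep-last + segmentation: concatenation equals the last 30 s
  es60 <- tiny_epochs(1, n_samples = 60 * fs, fs = fs, labels = "high")
  last30 <- keep_last(es60, 30)
  seg5 <- segment_epochs(last30, 5)
  expect_equal(n_epochs(seg5), 6)
  joined <- do.call(c, lapply(1:6, function(i) seg5$data[i, 1, ]))
  expect_equal(joined, es60$data[1, 1, (30 * fs + 1):(60 * fs)])
  expect_error(segment_epochs(es, 31), "longer than epoch")
})

test_that("preprocessing commutes with epoch subsetting", {
  es <- tiny_epochs(4)
  chain <- function(x) average_reference(bandpass_filter(x, 1, 40))
  whole <- chain(es)
  part <- chain(subset_epochs(es, c(1, 3)))
  expect_equal(part$data, whole$data[c(1, 3), , , drop = FALSE], tolerance = 1e-12)
})

test_that("the ocular-artifact hook defaults to the identity", {
  es <- tiny_epochs(2)
  expect_identical(remove_eog(es), es)
  flip <- remove_eog(es, function(x) { x$data <- -x$data; x })
  expect_equal(flip$data, -es$data)
})
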