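test_that("montage presets satisfy their structural invariants", {
  esd <- montage_preset("esd")
  expect_length(esd$channel_labels, 62)
  expect_equal(nrow(esd$symmetric_pairs), 27)
  expect_false(anyDuplicated(esd$channel_labels) > 0)
  expect_true(all(as.vector(esd$symmetric_pairs) %in% esd$channel_labels))

  deap <- montage_preset("deap")
  expect_length(deap$channel_labels, 32)
  expect_equal(nrow(deap$symmetric_pairs), 14)
  expect_true(all(esd$region_map %in%
    c("frontal", "temporal", "central", "parietal", "occipital")))
})

test_that("montage constructor rejects malformed inputs", {
  expect_error(montage(c("A", "A"), matrix(character(0), 0, 2), c(A = "frontal")),
               "duplicate")
  expect_error(montage(c("A", "B"), rbind(c("A", "C")),
                       c(A = "frontal", B = "frontal")), "not in channel_labels")
  expect_error(montage(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C")),
                       c(A = "frontal", B = "frontal", C = "frontal")),
               "more than one")
})

test_that("band scheme presets carry the canonical band edges", {
  b6 <- band_scheme_preset("esd6")
  expect_equal(b6$band, c("delta", "theta", "alpha", "beta", "gamma", "high_gamma"))
  expect_equal(b6$f_low, c(1, 4, 8, 13, 30, 50))
  expect_equal(b6$f_high, c(4, 8, 13, 30, 50, 80))
  b4 <- band_scheme_preset("deap4")
  expect_equal(b4$band, c("theta", "alpha", "beta", "gamma"))
  expect_error(band_scheme(data.frame(band = "x", f_low = 5, f_high = 5)),
               "degenerate")
})

test_that("feature registry enumerates deterministically with the expected counts", {
  m <- montage_preset("esd"); b <- band_scheme_preset("esd6")
  reg <- feature_registry(m, b)
  expect_identical(reg, feature_registry(m, b))  # pure function

  time_rows <- reg[reg$family == "time", ]
  expect_equal(nrow(time_rows), 8 * 62)
  expect_setequal(unique(time_rows$feature),
                  c("std", "fir_dif", "n_fir_dif", "sec_dif", "n_sec_dif",
                    "fd", "apen", "samen"))

  net_rows <- reg[reg$family == "network", ]
  expect_equal(nrow(net_rows), 3 * 4 * 6)  # methods x properties x bands
  # per-network: 4 properties x 6 bands
  expect_equal(sum(startsWith(net_rows$feature, "pearson")), 4 * 6)

  # asymmetry columns: 27 pairs per per-electrode base feature
  da_rows <- reg[reg$family == "DA", ]
  base_feats <- 8 + 2 * 6 + 6  # time + (psd, power) x bands + de x bands
  expect_equal(nrow(da_rows), 27 * base_feats)
  expect_false(anyDuplicated(reg$id) > 0)

  only_time <- feature_registry(m, b, families = "time")
  expect_setequal(unique(only_time$family), "time")
})

test_that("container round trip is lossless including ratings and their absence", {
  es <- tiny_epochs(3)
  p <- withr::local_tempfile()
  save_container(es, p)
  back <- load_container(p)
  expect_identical(back$data, es$data)
  expect_identical(back$labels, es$labels)
  expect_identical(back$fs, es$fs)
  expect_identical(back$montage$channel_labels, es$montage$channel_labels)
  expect_identical(back$montage$symmetric_pairs, es$montage$symmetric_pairs)
  expect_null(back$ratings)

  es$ratings <- tibble::tibble(valence = c(6, 3, 7), arousal = c(4, 5, 5.5))
  save_container(es, p)
  expect_equal(load_container(p)$ratings, es$ratings)
})

test_that("container load fails loudly on truncation and version mismatch", {
  es <- tiny_epochs(2)
  p <- withr::local_tempfile()
  save_container(es, p)
  # truncate the data file
  bin <- paste0(p, ".bin")
  raw <- readBin(bin, "raw", file.info(bin)$size)
  writeBin(raw[1:(length(raw) - 16)], bin)
  expect_error(load_container(p), "truncated|expected")
  # version mismatch
  save_container(es, p)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  meta$version <- 99
  jsonlite::write_json(meta, paste0(p, ".json"), auto_unbox = TRUE)
  expect_error(load_container(p), "version")
})

test_that("EDF write/read round-trips labels, sample count and values to quantization", {
  es <- tiny_epochs(2, n_samples = 128)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(es, p)
  back <- read_edf(p)
  expect_identical(back$montage$channel_labels, es$montage$channel_labels)
  expect_equal(dim(back$data)[3], 2 * 128)  # concatenated epochs
  rng <- diff(range(es$data))
  joined <- cbind(es$data[1, , ], es$data[2, , ])
  expect_lt(max(abs(back$data[1, , ] - joined)), rng / 32768)
})

test_that("EDF reader computes n_samples from rate and duration and rejects bad headers", {
  # 62-channel, 600 Hz, 10 s recording
  m <- montage_preset("esd")
  es <- epoch_set(array(rnorm(62 * 6000), c(1, 62, 6000)), fs = 600,
                  montage = m, labels = "recording")
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(es, p)
  back <- read_edf(p)
  expect_equal(dim(back$data)[3], 6000)
  expect_equal(back$fs, 600)

  # duplicate channel labels in the header -> error
  raw <- readBin(p, "raw", file.info(p)$size)
  lab1 <- charToRaw(formatC(m$channel_labels[1], width = -16))
  raw[(256 + 16 + 1):(256 + 32)] <- lab1  # overwrite 2nd label with 1st
  writeBin(raw, p)
  expect_error(read_edf(p), "duplicate")

  # garbage version field -> format error naming the field
  raw[1:8] <- charToRaw("XXXXXXXX")
  writeBin(raw, p)
  expect_error(read_edf(p), "version")
})

test_that("epoch subsetting keeps labels, ratings and montage consistent", {
  es <- tiny_epochs(4)
  es$ratings <- tibble::tibble(valence = 1:4, arousal = 4:1)
  sub <- subset_epochs(es, c(2, 4))
  expect_equal(sub$labels, es$labels[c(2, 4)])
  expect_equal(sub$ratings$valence, c(2, 4))
  chs <- subset_channels(es, c("F3", "T7"))
  expect_equal(n_channels(chs), 2)
  expect_equal(nrow(chs$montage$symmetric_pairs), 0)  # broken pairs dropped
  expect_error(subset_channels(es, "Oz"), "unknown|no requested")
})
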