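test_that("mutual information is the label entropy for a perfectly informative feature", {
  y <- rep(c("a", "b"), each = 150)
  x <- as.numeric(factor(y)) + rnorm(300, sd = 1e-6)  # feature == label code
  expect_equal(mutual_information(x, y), log(2), tolerance = 0.01)
  # unbalanced labels: MI = H(y)
  y2 <- rep(c("a", "b"), times = c(225, 75))
  x2 <- as.numeric(factor(y2)) + rnorm(300, sd = 1e-6)
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(mutual_information(x2, y2), h, tolerance = 0.02)
})

test_that("mutual information is near zero for independent features and invariant to monotone maps", {
  set.seed(41)
  y <- rep(c("a", "b"), each = 150)
  x <- rnorm(300)
  expect_lt(mutual_information(x, y), 0.05)
  shifted <- exp(3 * x + 1)  # strictly monotone transform
  expect_equal(mutual_information(shifted, y), mutual_information(x, y),
               tolerance = 1e-12)
  expect_equal(mutual_information(rep(2, 300), y), 0)
})

test_that("greedy mRMR starts at max relevance and matches the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 120
    y <- rep(c("a", "b", "c"), length.out = n)
    X <- matrix(rnorm(n * 6), n, 6)
    X[, 2] <- X[, 2] + 1.5 * as.numeric(factor(y))     # informative
    X[, 5] <- X[, 5] + 0.8 * as.numeric(factor(y))     # weakly informative
    got <- mrmr_rank(X, y, k = 6)
    rel <- sapply(1:6, function(j) mutual_information(X[, j], y))
    expect_equal(got[1], which.max(rel))
    expect_equal(got, oracle_mrmr(X, y, k = 6))
  }
})

test_that("the redundancy penalty suppresses duplicated features", {
  set.seed(43)
  n <- 300
  y <- rep(c("a", "b"), each = n / 2)
  strong <- rnorm(n) + 2 * as.numeric(factor(y))
  weak <- rnorm(n) + 0.8 * as.numeric(factor(y))
  X <- cbind(strong, strong, weak)  # col 2 duplicates col 1
  r <- mrmr_rank(X, y, k = 2)
  expect_equal(r[1], 1)   # strongest, lowest index on tie
  expect_equal(r[2], 3)   # duplicate penalized below the weaker feature
})

test_that("mrmr_rank validates its arguments", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), 10)
  expect_error(mrmr_rank(X, y, k = 0), "positive")
  expect_error(mrmr_rank(X, y, k = 3), "exceeds")
  expect_error(mrmr_rank(X, rep("a", 20), k = 1), "2 classes")
})

test_that("electrode frequency counting conserves counts and breaks ties by montage order", {
  electrodes <- c("F3", "F4", "T7", "T8", "O1")
  # all subjects agree
  same <- replicate(5, c("T7", "F3", "F4", "T8", "O1"), simplify = FALSE)
  ef <- electrode_frequency(same, k = 2, electrodes)
  expect_equal(ef$counts$count[match(c("T7", "F3"), ef$counts$electrode)], c(5, 5))
  expect_equal(sum(ef$counts$count), 5 * 2)  # conservation: n_subjects x k
  expect_setequal(ef$top, c("T7", "F3"))
  # tie between F4 and T8 resolved toward montage order (F4 first)
  mixed <- list(c("F3", "F4"), c("F3", "T8"))
  ef2 <- electrode_frequency(mixed, k = 2, electrodes)
  expect_equal(ef2$top, c("F3", "F4"))
  expect_error(electrode_frequency(list("F3"), k = 2, electrodes), "shorter")
})

test_that("cohort electrode selection recovers informative electrodes from feature matrices", {
  # synthetic cohort at the feature level: 5 subjects, 10 electrodes,
  # electrodes 2 and 7 carry class information
  set.seed(44)
  electrodes <- paste0("E", 1:10)
  m <- montage(electrodes, matrix(character(0), 0, 2),
               stats::setNames(rep("central", 10), electrodes))
  b <- band_scheme_preset("deap4")
  fms <- lapply(1:5, function(s) {
    n <- 60
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 10), n, 10)
    X[, 2] <- X[, 2] + 2 * as.numeric(factor(y))
    X[, 7] <- X[, 7] + 2 * as.numeric(factor(y))
    meta <- tibble::tibble(family = "time", feature = "fir_dif",
                           band = NA_character_, electrode = electrodes)
    meta$id <- paste("time", "fir_dif", "-", electrodes, sep = "|")
    colnames(X) <- meta$id
    eegvalence:::new_feature_matrix(X, meta, y, sprintf("S%02d", s))
  })
  sel <- select_electrodes(fms, "time", "fir_dif", sizes = c(1, 2, 4))
  expect_true(all(c("E2", "E7") %in% sel$sets[["2"]]))
  expect_equal(sum(sel$counts[["2"]]$count), 5 * 2)
  expect_s3_class(tidy(sel), "tbl_df")
})
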