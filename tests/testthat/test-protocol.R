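test_that("one-vs-rest resampling builds balanced, seeded, within-pool datasets", {
  y <- five_class_labels(30)  # 30 EN + 120 rest
  sets <- make_en_vs_rest(y, seed = 3)
  expect_length(sets, 4)
  for (s in sets) {
    expect_length(s$idx, 60)  # 30 + 30 balanced
    expect_equal(sum(s$y == "EN"), 30)
    expect_equal(sum(s$y == "rest"), 30)
    expect_true(all(s$idx[s$y == "rest"] %in% which(y != "EN")))
  }
  # the four rest draws are distinct under a fixed seed
  draws <- lapply(sets, function(s) sort(s$idx[s$y == "rest"]))
  expect_equal(length(unique(draws)), 4)
  # seeded reproducibility
  expect_identical(make_en_vs_rest(y, seed = 3), sets)
  expect_error(make_en_vs_rest(rep("MN", 10)), "missing")
})

test_that("valence sample selection windows arousal, splits on 5 and balances classes", {
  arr <- array(rnorm(25 * 2 * 32), c(25, 2, 32))
  labs <- c("a", "b")
  es <- epoch_set(arr, 128, montage(labs, matrix(character(0), 0, 2),
                                    stats::setNames(rep("central", 2), labs)),
                  rep("x", 25))
  # 12 high + 8 low inside the window, plus excluded trials
  es$ratings <- tibble::tibble(
    valence = c(rep(7, 12), rep(3, 8), 5, 5, 8, 2, 7),
    arousal = c(rep(5, 12), rep(4, 8), 5, 5, 9, 1, 6.5))
  out <- select_deap_samples(es, seed = 2)
  expect_equal(sum(out$labels == "high"), 8)
  expect_equal(sum(out$labels == "low"), 8)
  # valence exactly 5 and out-of-window arousal excluded
  expect_equal(n_epochs(out), 16)
  bad <- es; bad$ratings$arousal <- 9
  expect_error(select_deap_samples(bad), "empty class")
  noratings <- tiny_epochs(2)
  expect_error(select_deap_samples(noratings), "no ratings")
})

test_that("stratified folds are balanced and sized within one of each other", {
  y <- five_class_labels(13)  # awkward class size
  fold <- eegvalence:::stratified_folds(y, 5, seed = 1)
  sizes <- table(fold)
  expect_lte(diff(range(sizes)), 1)
  for (cls in unique(y)) {
    per <- table(fold[y == cls])
    expect_lte(diff(range(per)), 1)
  }
  expect_error(eegvalence:::stratified_folds(rep(c("a", "b"), c(3, 50)), 5, 1),
               "fewer than")
})

test_that("perfectly separable classes reach accuracy 1 and results are seed-deterministic", {
  set.seed(51)
  n <- 100
  y <- rep(c("p", "q"), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == "p", 1] <- X[y == "p", 1] + 20  # disjoint clusters
  res <- crossval_accuracy(X, y, classifiers = "svm_linear", seed = 7)
  expect_equal(mean(res$accuracy), 1)
  res2 <- crossval_accuracy(X, y, classifiers = "svm_linear", seed = 7)
  expect_identical(res, res2)
  expect_error(crossval_accuracy(X, rep("p", n)), "2 classes")
})

test_that("all six classifiers run on a five-class problem and report valid accuracies", {
  set.seed(52)
  n <- 75
  y <- five_class_labels(15)
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 1] <- X[, 1] + as.numeric(factor(y))
  res <- crossval_accuracy(X, y, classifiers = c("svm_linear", "knn", "rf",
                                                 "nb", "dac", "boost"),
                           seed = 9, task = "five_class")
  expect_equal(nrow(res), 6 * 5)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  g <- glance(res)
  expect_equal(nrow(g), 6)
  expect_true(all(g$n_folds == 5))
})

test_that("the one-vs-rest protocol averages over resamples and folds", {
  es <- generate_subject(small_esd_spec(n_trials = 6), 1)
  fm <- extract_features(subset_channels(es, c("F3", "F4", "T7", "T8")),
                         families = "time")
  res <- run_en_vs_rest(fm, classifiers = "svm_linear", seed = 4)
  expect_equal(nrow(res), 4 * 5)  # 4 resamples x 5 folds
  expect_setequal(unique(res$resample), 1:4)
  expect_identical(run_en_vs_rest(fm, classifiers = "svm_linear", seed = 4),
                   res)
})

test_that("reduced electrode runs reproduce the full run on the complete set", {
  set.seed(53)
  es <- generate_subject(small_esd_spec(n_trials = 6, epoch_length = 1), 1)
  fm <- extract_features(es, families = "timefreq")
  meta <- column_meta(fm)
  all_els <- es$montage$channel_labels
  sets <- list(all = all_els, four = c("F3", "F4", "T7", "T8"), one = "F3")
  res <- reduced_electrode_run(fm, sets, "timefreq", "de", band = "high_gamma",
                               classifiers = "svm_linear", seed = 6)
  ids <- meta$id[meta$family == "timefreq" & meta$band == "high_gamma"]
  full <- crossval_accuracy(as.matrix(fm)[, ids], epoch_labels(fm),
                            classifiers = "svm_linear", seed = 6)
  expect_equal(res$accuracy[res$feature_set == "all"], full$accuracy)
  # the one-electrode run uses exactly one column
  expect_equal(sum(meta$family == "timefreq" & meta$band == "high_gamma" &
                     meta$electrode == "F3"), 1)
  expect_setequal(unique(res$feature_set), c("all", "four", "one"))
})

test_that("tidy and autoplot methods return the expected shapes", {
  set.seed(54)
  y <- rep(c("a", "b"), each = 20)
  X <- matrix(rnorm(40 * 3), 40, 3)
  res <- crossval_accuracy(X, y, classifiers = c("svm_linear", "knn"), seed = 2)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "protocol_result"))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
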