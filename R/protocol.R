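# Cross-validated classification protocols: stratified k-fold CV with
# training-fold-only standardization, six shallow classifiers,
# one-vs-rest balanced resampling, rating-windowed high/low valence
# sample construction, and reduced-electrode runs.

CLASSIFIERS <- c("svm_linear", "knn", "rf", "nb", "dac", "boost")

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Stratified fold assignment: per class, a seeded shuffle dealt
# round-robin with a rotating global offset so overall fold sizes differ
# by at most one.
stratified_folds <- function(y, n_folds, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  start <- 0L
  with_local_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      if (length(idx) < n_folds) {
        stop("stratified_folds: class '", cls, "' has ", length(idx),
             " samples, fewer than ", n_folds, " folds")
      }
      idx <- sample(idx)
      fold[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
      start <- (start + length(idx)) %% n_folds
    }
  })
  fold
}

fit_predict <- function(classifier, x_train, y_train, x_test, seed) {
  y_train <- factor(y_train)
  lev <- levels(y_train)
  with_local_seed(seed, switch(
    classifier,
    svm_linear = {
      fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = 1,
                        scale = FALSE)
      as.character(predict(fit, x_test))
    },
    knn = as.character(class::knn(x_train, x_test, y_train, k = 5)),
    rf = {
      fit <- randomForest::randomForest(x_train, y_train, ntree = 100)
      as.character(predict(fit, x_test))
    },
    nb = {
      fit <- e1071::naiveBayes(x_train, y_train)
      as.character(predict(fit, x_test))
    },
    dac = {
      fit <- suppressWarnings(MASS::lda(x_train, grouping = y_train))
      as.character(predict(fit, x_test)$class)
    },
    boost = {
      yt <- as.integer(y_train) - 1L
      binary <- length(lev) == 2
      params <- list(max_depth = 1, eta = 0.3, nthread = 1,
                     objective = if (binary) "binary:logistic" else "multi:softmax")
      if (!binary) params$num_class <- length(lev)
      dtrain <- xgboost::xgb.DMatrix(x_train, label = yt, nthread = 1)
      fit <- xgboost::xgb.train(params, dtrain, nrounds = 50, verbose = 0)
      pred <- predict(fit, xgboost::xgb.DMatrix(x_test, nthread = 1))
      if (binary) lev[as.integer(pred > 0.5) + 1L] else lev[as.integer(pred) + 1L]
    },
    stop("unknown classifier: ", classifier)
  ))
}

#' Stratified cross-validated classification accuracy
#'
#' Runs stratified `n_folds`-fold cross-validation of one or more shallow
#' classifiers on a feature matrix. Features are z-scored with
#' training-fold statistics only (no information from test folds leaks
#' into standardization). Fold assignment, subsampling and classifier
#' fitting are fully determined by `seed`.
#'
#' Classifiers: `"svm_linear"` (C-SVC, linear kernel, C = 1), `"knn"`
#' (k = 5), `"rf"` (random forest, 100 trees), `"nb"` (Gaussian naive
#' Bayes), `"dac"` (linear discriminant analysis), `"boost"`
#' (gradient-boosted stumps, 50 rounds).
#'
#' @param data Feature matrix (data frame or matrix, epochs x features).
#' @param labels Per-row class labels; defaults to `epoch_labels(data)`
#'   for a `feature_matrix`.
#' @param classifiers Subset of the six classifier names.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param standardize Z-score with training-fold statistics (default
#'   `TRUE`).
#' @param task Label stored in the result (e.g. `"five_class"`).
#' @return A `protocol_result` tibble with columns `subject`, `task`,
#'   `classifier`, `fold`, `accuracy`.
#' @export
crossval_accuracy <- function(data, labels = NULL,
                              classifiers = "svm_linear", n_folds = 5,
                              seed = 1, standardize = TRUE,
                              task = "cv") {
  if (is.null(labels)) labels <- epoch_labels(data)
  if (is.null(labels)) stop("crossval_accuracy: labels required")
  subject <- attr(data, "subject_id") %||% "S01"
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("crossval_accuracy: non-finite feature values")
  y <- as.character(labels)
  if (length(unique(y)) < 2) stop("crossval_accuracy: need >= 2 classes")
  classifiers <- match.arg(classifiers, CLASSIFIERS, several.ok = TRUE)
  fold <- stratified_folds(y, n_folds, seed)
  rows <- list()
  for (cl in classifiers) {
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (standardize) {
        mu <- colMeans(Xtr)
        sdv <- apply(Xtr, 2, sd)
        sdv[sdv == 0] <- 1
        Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
        Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
      }
      pred <- fit_predict(cl, Xtr, y[tr], Xte,
                          seed = seed + 131L * f + 17L * match(cl, CLASSIFIERS))
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = subject, task = task, classifier = cl, fold = f,
        accuracy = mean(pred == y[te]))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("protocol_result", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Balanced one-vs-rest resampling datasets
#'
#' Builds the balanced binary datasets for separating one target class
#' from the mixture of the others: all target-class epochs versus an
#' equal-size subsample of the pooled remaining classes, drawn without
#' replacement; repeated `n_resamples` times (seeded, draws differ across
#' resamples).
#'
#' @param labels Per-epoch class labels containing the target class and at
#'   least one other class.
#' @param target Target class name (default `"EN"`).
#' @param n_resamples Number of balanced draws (default 4, one per mixed
#'   class when the rest pools four classes).
#' @param seed Integer seed.
#' @param balanced If `FALSE`, each dataset uses the full rest pool
#'   (unbalanced reading).
#' @return A list of length `n_resamples`; each element has `idx` (epoch
#'   indices into the original set) and `y` (binary labels `target` /
#'   `"rest"`).
#' @export
make_en_vs_rest <- function(labels, target = "EN", n_resamples = 4,
                            seed = 1, balanced = TRUE) {
  y <- as.character(labels)
  if (!target %in% y) stop("make_en_vs_rest: target class '", target, "' missing")
  pos <- which(y == target)
  pool <- which(y != target)
  if (!length(pool)) stop("make_en_vs_rest: no rest-class epochs")
  if (balanced && length(pool) < length(pos)) {
    stop("make_en_vs_rest: rest pool smaller than target class")
  }
  lapply(seq_len(n_resamples), function(r) {
    neg <- if (balanced) {
      with_local_seed(seed + 1009L * r, sample(pool, length(pos)))
    } else pool
    idx <- c(pos, sort(neg))
    list(idx = idx, y = ifelse(y[idx] == target, target, "rest"))
  })
}

#' Run the one-vs-rest protocol on a feature matrix
#'
#' Applies [make_en_vs_rest()] and averages stratified 5-fold CV accuracy
#' over the balanced resamples (the "4 x 5-fold" scheme).
#'
#' @inheritParams crossval_accuracy
#' @inheritParams make_en_vs_rest
#' @param fm A `feature_matrix` (or data frame plus `labels`).
#' @return A `protocol_result` tibble with a `resample` column.
#' @export
run_en_vs_rest <- function(fm, labels = NULL, target = "EN",
                           classifiers = "svm_linear", n_resamples = 4,
                           n_folds = 5, seed = 1) {
  if (is.null(labels)) labels <- epoch_labels(fm)
  sets <- make_en_vs_rest(labels, target, n_resamples, seed)
  out <- dplyr::bind_rows(lapply(seq_along(sets), function(r) {
    s <- sets[[r]]
    res <- crossval_accuracy(as.matrix(fm)[s$idx, , drop = FALSE], s$y,
                             classifiers = classifiers, n_folds = n_folds,
                             seed = seed + r, task = "en_vs_rest")
    res$subject <- attr(fm, "subject_id") %||% "S01"
    res$resample <- r
    res
  }))
  class(out) <- c("protocol_result", class(out))
  out
}

#' Construct the high/low valence sample set from rated trials
#'
#' Implements the rating-window sample selection for continuously rated
#' trials: keep trials with arousal inside `arousal_window`, label them
#' `high` (valence > threshold) or `low` (valence < threshold; trials at
#' exactly the threshold are dropped), then randomly down-sample the
#' majority class to the minority count (seeded).
#'
#' @param eps An [epoch_set] with a `ratings` tibble.
#' @param arousal_window Numeric `c(lo, hi)` (default `c(3.5, 6)`).
#' @param valence_threshold Rating threshold (default 5).
#' @param seed Integer seed for the down-sampling draw.
#' @return A balanced [epoch_set] with labels `high` / `low`.
#' @export
select_deap_samples <- function(eps, arousal_window = c(3.5, 6),
                                valence_threshold = 5, seed = 1) {
  stopifnot(inherits(eps, "epoch_set"))
  if (is.null(eps$ratings)) stop("select_deap_samples: epoch_set has no ratings")
  a <- eps$ratings$arousal; v <- eps$ratings$valence
  keep <- a >= arousal_window[1] & a <= arousal_window[2] & v != valence_threshold
  hi <- which(keep & v > valence_threshold)
  lo <- which(keep & v < valence_threshold)
  if (!length(hi) || !length(lo)) {
    stop("select_deap_samples: empty class after arousal/valence windowing ",
         "(high = ", length(hi), ", low = ", length(lo), ")")
  }
  n <- min(length(hi), length(lo))
  with_local_seed(seed, {
    if (length(hi) > n) hi <- sort(sample(hi, n))
    if (length(lo) > n) lo <- sort(sample(lo, n))
  })
  idx <- sort(c(hi, lo))
  out <- subset_epochs(eps, idx)
  out$labels <- ifelse(eps$ratings$valence[idx] > valence_threshold, "high", "low")
  out
}

#' Cross-validated accuracy on reduced electrode sets
#'
#' Restricts a per-electrode base feature to each electrode subset (for
#' example the mRMR top-1/4/8/16 sets plus all electrodes) and runs the
#' same cross-validation on each restriction. The full-montage set
#' reproduces the unrestricted run exactly under the same seed.
#'
#' @inheritParams crossval_accuracy
#' @param fm A `feature_matrix`.
#' @param electrode_sets Named list of electrode-label vectors.
#' @param family,feature,band The base feature to restrict.
#' @return A `protocol_result` tibble with a `feature_set` column naming
#'   each electrode set.
#' @export
reduced_electrode_run <- function(fm, electrode_sets, family, feature,
                                  band = NA, labels = NULL,
                                  classifiers = "svm_linear",
                                  n_folds = 5, seed = 1, task = "cv") {
  if (is.null(labels)) labels <- epoch_labels(fm)
  meta <- column_meta(fm)
  sel <- meta$family == family & meta$feature == feature &
    (if (is.na(band)) is.na(meta$band) else !is.na(meta$band) & meta$band == band)
  if (!any(sel)) stop("reduced_electrode_run: no columns match the base feature")
  out <- dplyr::bind_rows(lapply(names(electrode_sets), function(nm) {
    els <- electrode_sets[[nm]]
    ids <- meta$id[sel & meta$electrode %in% els]
    if (!length(ids)) stop("reduced_electrode_run: electrode set '", nm, "' matches no columns")
    res <- crossval_accuracy(as.matrix(fm)[, ids, drop = FALSE], labels,
                             classifiers = classifiers, n_folds = n_folds,
                             seed = seed, task = task)
    res$subject <- attr(fm, "subject_id") %||% "S01"
    res$feature_set <- nm
    res
  }))
  class(out) <- c("protocol_result", class(out))
  out
}

#' @rdname crossval_accuracy
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @method tidy protocol_result
#' @export
tidy.protocol_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname crossval_accuracy
#' @method glance protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(unclass(x)),
                    dplyr::across(dplyr::any_of(c("task", "feature_set", "classifier")))),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = sd(.data$accuracy),
    n_folds = dplyr::n(),
    .groups = "drop")
}

#' @rdname crossval_accuracy
#' @param object A `protocol_result`.
#' @method autoplot protocol_result
#' @export
autoplot.protocol_result <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  xvar <- if ("feature_set" %in% names(df)) "feature_set" else "classifier"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$accuracy,
                                   fill = .data$classifier)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "fold accuracy", x = NULL) +
    ggplot2::theme_minimal()
}
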