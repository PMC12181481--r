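#' Stratified train/test split
#'
#' The test partition is held out from every selection and tuning step:
#' feature selection runs on the training rows only.
#'
#' @param X data.frame of numeric features.
#' @param y binary labels.
#' @param test_fraction fraction held out, in `(0, 1)`.
#' @param seed integer seed.
#' @return list with `train` and `test`, each a list of `X`, `y`, `idx`
#'   (row indices into the input).
#' @export
split_cohort <- function(X, y, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  y <- as_binary_factor(y)
  if (min(table(y)) < 2L) stop("each class needs at least 2 members", call. = FALSE)
  set.seed(fan_seed(seed, "split"))
  test_idx <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_test <- round(test_fraction * length(idx))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  list(
    train = list(X = X[train_idx, , drop = FALSE], y = y[train_idx], idx = train_idx),
    test = list(X = X[test_idx, , drop = FALSE], y = y[test_idx], idx = test_idx)
  )
}

#' Classification metrics from labels and scores
#'
#' Accuracy, precision and recall are computed from the confusion counts with
#' the positive class (second level; `PositiveAger` when present) as the
#' reference; AUC comes from the continuous scores. All four are reported as
#' percentages.
#'
#' @param y_true true labels (two-level factor).
#' @param y_pred predicted labels.
#' @param scores continuous positive-class scores.
#' @return named numeric vector `accuracy, precision, recall, auc` in percent.
#' @export
classification_metrics <- function(y_true, y_pred, scores) {
  y_true <- as_binary_factor(y_true)
  if (nlevels(droplevels(y_true)) < 2L) {
    stop("test set contains a single class", call. = FALSE)
  }
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  pos <- positive_class(y_true)
  tp <- sum(y_pred == pos & y_true == pos)
  fp <- sum(y_pred == pos & y_true != pos)
  fn <- sum(y_pred != pos & y_true == pos)
  acc <- mean(y_pred == y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(accuracy = 100 * acc, precision = 100 * prec, recall = 100 * rec,
    auc = 100 * auc_score(y_true, scores))
}

#' Evaluate a fitted classifier on held-out data
#'
#' @param fit a [fit_classifier()] result.
#' @param X_test,y_test held-out features and labels (both classes present).
#' @return named numeric vector of percent metrics (see
#'   [classification_metrics()]).
#' @export
evaluate_classifier <- function(fit, X_test, y_test) {
  if (!nrow(X_test)) stop("empty test set", call. = FALSE)
  classification_metrics(y_test, predict_classes(fit, X_test),
                         predict_scores(fit, X_test))
}

#' Impurity-based feature importance ranking
#'
#' Mean-decrease-in-impurity importances of a fitted random forest,
#' normalized to sum to one and sorted descending; the top slice is annotated
#' with each feature's category and visit tag for plotting.
#'
#' @param fit a [fit_classifier()] result with `kind = "rf"`.
#' @param meta optional feature metadata data.frame (`feature, category,
#'   visit`).
#' @param top_k ranking length (default 15).
#' @return data.frame `feature, importance, category, visit`, importance
#'   non-increasing.
#' @export
importance_ranking <- function(fit, meta = NULL, top_k = 15L) {
  if (!inherits(fit, "cogsel_fit") || fit$spec$kind != "rf") {
    stop("importance ranking needs a fitted random forest", call. = FALSE)
  }
  imp <- fit$model$variable.importance
  if (is.null(imp)) stop("forest was fitted without importance", call. = FALSE)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  imp <- sort(imp, decreasing = TRUE)
  top <- utils::head(imp, top_k)
  out <- data.frame(feature = names(top), importance = as.numeric(top),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    m <- match(out$feature, meta$feature)
    out$category <- meta$category[m]
    out$visit <- meta$visit[m]
  } else {
    out$category <- NA_character_
    out$visit <- NA_character_
  }
  out
}

#' Partial dependence of the positive-class probability on one feature
#'
#' For each grid value `v` the feature is clamped to `v` in every row of the
#' table and the mean predicted positive-class score is recorded,
#' marginalizing over the remaining features. A 0.5 threshold on the
#' probability scale separates the predicted classes.
#'
#' @param fit a fitted classifier (anything with a [predict_scores()] method).
#' @param X data.frame over which to marginalize.
#' @param feature feature name.
#' @param grid_size number of grid points (unique observed values are used
#'   when fewer).
#' @return data.frame `value, prob` of class `partial_dependence` with
#'   attribute `threshold = 0.5`.
#' @export
partial_dependence <- function(fit, X, feature, grid_size = 20L) {
  if (!feature %in% names(X)) stop("feature '", feature, "' not in table", call. = FALSE)
  v <- X[[feature]]
  u <- sort(unique(v))
  if (length(u) == 1L) {
    warning("feature '", feature, "' is constant; single-point curve", call. = FALSE)
    grid <- u
  } else if (length(u) <= grid_size) {
    grid <- u
  } else {
    grid <- seq(min(v), max(v), length.out = grid_size)
  }
  prob <- vapply(grid, function(g) {
    Xg <- X
    Xg[[feature]] <- g
    mean(predict_scores(fit, Xg))
  }, numeric(1))
  structure(data.frame(value = grid, prob = prob),
            class = c("partial_dependence", "data.frame"), threshold = 0.5)
}

#' Benchmark configuration
#'
#' @param stage_a a [stage_a_config()].
#' @param stage_b a [stage_b_config()].
#' @param k_range SFS subset-size range for the stage-C spaces (upper end is
#'   clipped to the available features at run time).
#' @param tune named hyperparameter dimensions per classifier kind, e.g.
#'   `list(rf = list(min.node.size = dim_categorical(c(1, 5))), svm = ...)`.
#' @param budget,n_init Bayesian-optimization budget per selector/classifier
#'   cell.
#' @param test_fraction held-out fraction.
#' @param n_folds CV folds shared by all stages.
#' @return object of class `benchmark_config`.
#' @export
benchmark_config <- function(stage_a = stage_a_config(),
                             stage_b = stage_b_config(),
                             k_range = c(2L, 15L),
                             tune = list(rf = list(), svm = list()),
                             budget = 10L, n_init = 4L,
                             test_fraction = 0.2, n_folds = 5L) {
  structure(list(stage_a = stage_a, stage_b = stage_b, k_range = k_range,
                 tune = tune, budget = as.integer(budget),
                 n_init = as.integer(n_init),
                 test_fraction = test_fraction, n_folds = as.integer(n_folds)),
            class = "benchmark_config")
}

# BO-tune classifier hyperparameters on a fixed feature set (no k dimension).
tune_classifier <- function(X, y, kind, tune_dims, budget, n_init, n_folds, seed) {
  if (!length(tune_dims)) {
    return(classifier_spec(kind = kind))
  }
  sp <- do.call(search_space, c(tune_dims, list(budget = budget, n_init = n_init,
                                                seed = fan_seed(seed, paste0("tune_", kind)))))
  attr(sp, "kind") <- kind
  attr(sp, "fixed") <- list()
  opt <- bayes_opt_tune(function(cfg) {
    cv_auc(X, y, config_to_spec(sp, cfg), n_folds = n_folds, seed = seed)$mean
  }, sp)
  config_to_spec(sp, opt$best_config)
}

#' Run the selector-by-classifier benchmark
#'
#' Reproduces the benchmark layout of the study design: a stratified 80/20
#' split, Stage A filtering applied once to the training partition and shared
#' by all selectors, then three selectors — `L1` (the Stage B subset), `SFS`
#' (Stage C run directly on the Stage A output) and `L1+SFS` (the full
#' chain) — each paired with a tuned random forest and a tuned SVM. Metrics
#' are computed on the untouched test rows.
#'
#' @param X data.frame of numeric features.
#' @param y binary labels.
#' @param config a [benchmark_config()].
#' @param seed integer top-level seed.
#' @return data.frame of class `benchmark_report` with 6 rows:
#'   `classifier, selector, N_f, accuracy, precision, recall, auc`
#'   (percent, full precision; use `print()` for the integer-rounded view).
#' @export
run_benchmark <- function(X, y, config = benchmark_config(), seed = 1L) {
  check_feature_table(X)
  y <- as_binary_factor(y)
  sp <- split_cohort(X, y, config$test_fraction, seed)
  tr <- sp$train; te <- sp$test

  A <- stage_a(tr$X, tr$y, config$stage_a)
  B <- stage_b(A$X, tr$y, config$stage_b, seed = fan_seed(seed, "bench_b"))
  sel <- list()
  sel[["L1"]] <- B$selected

  clip_range <- function(p) c(min(config$k_range[1], p), min(config$k_range[2], p))
  rows <- list()
  for (kind in c("rf", "svm")) {
    kr_sfs <- clip_range(ncol(A$X))
    sfs_space <- stage_c_space(kind, kr_sfs, tune = config$tune[[kind]],
                               budget = config$budget, n_init = config$n_init,
                               seed = fan_seed(seed, paste0("sfs_", kind)))
    C_sfs <- stage_c(A$X, tr$y, sfs_space, n_folds = config$n_folds,
                     seed = fan_seed(seed, paste0("sfsc_", kind)))

    kr_full <- clip_range(length(B$selected))
    full_space <- stage_c_space(kind, kr_full, tune = config$tune[[kind]],
                                budget = config$budget, n_init = config$n_init,
                                seed = fan_seed(seed, paste0("full_", kind)))
    C_full <- stage_c(A$X[, B$selected, drop = FALSE], tr$y, full_space,
                      n_folds = config$n_folds,
                      seed = fan_seed(seed, paste0("fullc_", kind)))

    cells <- list(
      `L1` = list(features = B$selected,
                  spec = tune_classifier(tr$X[, B$selected, drop = FALSE], tr$y,
                                         kind, config$tune[[kind]],
                                         config$budget, config$n_init,
                                         config$n_folds, fan_seed(seed, paste0("l1_", kind)))),
      `SFS` = list(features = C_sfs$selected, spec = C_sfs$best_spec),
      `L1+SFS` = list(features = C_full$selected, spec = C_full$best_spec)
    )
    for (selname in names(cells)) {
      cell <- cells[[selname]]
      fit <- fit_classifier(cell$spec, tr$X[, cell$features, drop = FALSE],
                            tr$y, seed = fan_seed(seed, paste0("fit_", kind, selname)))
      m <- evaluate_classifier(fit, te$X[, cell$features, drop = FALSE], te$y)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = toupper(kind), selector = selname,
        N_f = length(cell$features),
        accuracy = m[["accuracy"]], precision = m[["precision"]],
        recall = m[["recall"]], auc = m[["auc"]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_report", "data.frame")
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark: selectors x classifiers (metrics in %, rounded)\n")
  y <- as.data.frame(x)
  for (col in c("accuracy", "precision", "recall", "auc")) y[[col]] <- round(y[[col]])
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
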