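#' Classifier specification
#'
#' A lightweight description of one of the two supported classifiers and its
#' hyperparameters, used by the wrapper selection stage, the Bayesian tuner
#' and the benchmark harness.
#'
#' @param kind `"rf"` (random forest, via ranger) or `"svm"` (RBF support
#'   vector machine, via e1071).
#' @param num.trees,min.node.size,mtry,max.depth random-forest
#'   hyperparameters (`mtry`/`max.depth` `NULL` = ranger defaults).
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses `1/p`).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rf", "svm"),
                            num.trees = 300L, min.node.size = 5L,
                            mtry = NULL, max.depth = NULL,
                            cost = 1, gamma = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind,
                 num.trees = as.integer(num.trees),
                 min.node.size = as.integer(min.node.size),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 max.depth = if (!is.null(max.depth)) as.integer(max.depth),
                 cost = cost, gamma = gamma),
            class = "classifier_spec")
}

# Stable string key for caching per-classifier work.
spec_key <- function(spec) {
  paste(spec$kind, spec$num.trees, spec$min.node.size,
        spec$mtry %||% "d", spec$max.depth %||% "d",
        format(spec$cost, digits = 12), format(spec$gamma %||% -1, digits = 12),
        sep = "|")
}

#' Fit a classifier on a feature table
#'
#' @param spec a [classifier_spec()].
#' @param X data.frame of numeric features.
#' @param y binary labels (positive class = second level, `PositiveAger`
#'   when present).
#' @param seed integer seed (forest randomness; the SVM fit is deterministic).
#' @return object of class `cogsel_fit`.
#' @export
fit_classifier <- function(spec, X, y, seed = 1L) {
  check_feature_table(X)
  y <- as_binary_factor(y)
  if (spec$kind == "rf") {
    model <- ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = spec$num.trees,
      min.node.size = spec$min.node.size,
      mtry = if (!is.null(spec$mtry)) min(spec$mtry, ncol(X)),
      max.depth = spec$max.depth %||% 0,
      importance = "impurity",
      seed = fan_seed(seed, "ranger"), num.threads = 1
    )
  } else {
    model <- e1071::svm(
      x = as.matrix(X), y = y, kernel = "radial",
      cost = spec$cost, gamma = spec$gamma %||% (1 / ncol(X)),
      scale = apply(X, 2, stats::sd) > 0
    )
  }
  structure(list(spec = spec, model = model, levels = levels(y),
                 features = names(X)),
            class = "cogsel_fit")
}

#' Continuous scores for the positive class
#'
#' Random forests return the out-of-bag-free predicted probability of the
#' positive class; SVMs return the decision value oriented so that larger
#' means more likely positive (rank-equivalent to a probability, which is all
#' AUC needs).
#'
#' @param fit object returned by [fit_classifier()] (S3 generic so tests can
#'   supply mock models).
#' @param X data.frame with at least the training features.
#' @return numeric score vector, higher = more likely positive class.
#' @export
predict_scores <- function(fit, X) UseMethod("predict_scores")

#' @export
predict_scores.cogsel_fit <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  pos <- fit$levels[2L]
  if (fit$spec$kind == "rf") {
    pr <- stats::predict(fit$model, data = X, num.threads = 1)$predictions
    as.numeric(pr[, pos])
  } else {
    pred <- stats::predict(fit$model, newdata = as.matrix(X), decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    lab <- colnames(dv)[1]
    first <- strsplit(lab, "/", fixed = TRUE)[[1]][1]
    if (identical(first, pos)) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
  }
}

#' Predicted class labels
#'
#' Thresholds the positive-class score at 0.5 (RF probability) or 0 (SVM
#' decision value).
#'
#' @inheritParams predict_scores
#' @return factor of predicted labels with the training levels.
#' @export
predict_classes <- function(fit, X) {
  s <- predict_scores(fit, X)
  thr <- if (fit$spec$kind == "rf") 0.5 else 0
  factor(ifelse(s > thr, fit$levels[2L], fit$levels[1L]), levels = fit$levels)
}

#' Stratified cross-validated AUC of a classifier spec
#'
#' @param X data.frame of numeric features.
#' @param y binary labels.
#' @param spec a [classifier_spec()].
#' @param n_folds stratified folds.
#' @param seed seed shared by fold assignment and classifier randomness.
#' @return list with `mean`, `sd`, and per-fold `auc`.
#' @export
cv_auc <- function(X, y, spec, n_folds = 5L, seed = 1L) {
  y <- as_binary_factor(y)
  folds <- stratified_folds(y, n_folds, seed)
  aucs <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    fit <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr], seed = seed)
    auc_score(y[!tr], predict_scores(fit, X[!tr, , drop = FALSE]))
  }, numeric(1))
  list(mean = mean(aucs), sd = stats::sd(aucs), auc = aucs)
}
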