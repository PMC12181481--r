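# Internal helpers shared across modules.

#' Derive a child seed from a top-level seed and a label
#'
#' Every stochastic step in the package draws its own seed from the single
#' user-facing seed via this deterministic hash, so that one `seed` argument
#' reproduces an entire analysis while keeping the stages' random streams
#' independent of each other.
#'
#' @param seed integer top-level seed.
#' @param label character tag naming the consumer (e.g. `"stage_b_folds"`).
#' @return an integer in `[0, 2^31)` usable with [set.seed()].
#' @keywords internal
fan_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((abs(as.numeric(seed)) %% 65011) * 32749 + h * 97) %% 2147483629L
}

# Coerce a binary outcome to a two-level factor with a well-defined positive
# class (second level). "PositiveAger" is promoted to positive when present.
as_binary_factor <- function(y, positive = NULL) {
  f <- as.factor(y)
  lev <- levels(droplevels(f))
  if (length(lev) != 2L) {
    stop("outcome must have exactly two observed classes, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if ("PositiveAger" %in% lev) "PositiveAger" else lev[2L]
  }
  if (!positive %in% lev) stop("positive class '", positive, "' not in labels")
  factor(f, levels = c(setdiff(lev, positive), positive))
}

positive_class <- function(y) levels(y)[2L]

#' Stratified cross-validation fold assignment
#'
#' @param y two-level factor outcome.
#' @param n_folds number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:n_folds`, one per observation,
#'   with class proportions balanced across folds.
#' @keywords internal
stratified_folds <- function(y, n_folds, seed) {
  y <- as.factor(y)
  if (min(table(y)) < n_folds) {
    stop("smallest class has fewer members (", min(table(y)),
         ") than folds (", n_folds, "); stratification impossible", call. = FALSE)
  }
  folds <- integer(length(y))
  set.seed(fan_seed(seed, "stratified_folds"))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# AUC of `scores` for separating the positive (second) level of `y`.
# pROC does the work; direction and levels are pinned so that larger scores
# mean "more likely positive" and no auto-flipping can occur.
auc_score <- function(y, scores) {
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2L)
  as.numeric(pROC::auc(
    response = y, predictor = as.numeric(scores),
    levels = levels(y), direction = "<", quiet = TRUE
  ))
}

# z-score columns with training statistics; zero-variance columns are left
# centered but unscaled (scale 1) so downstream fits see an exact zero column.
standardize_train <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(x = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

standardize_apply <- function(X, std) {
  X <- as.matrix(X)[, names(std$center), drop = FALSE]
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

check_feature_table <- function(X) {
  if (!is.data.frame(X)) stop("feature table must be a data.frame", call. = FALSE)
  bad <- names(X)[!vapply(X, is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric feature columns: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(X)) stop("feature table contains missing values", call. = FALSE)
  invisible(X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
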