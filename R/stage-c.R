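#' Sequential forward feature selection
#'
#' Grows a feature subset greedily: at each step the candidate feature whose
#' addition maximizes the stratified cross-validated AUC of the supplied
#' classifier is added, until the subset reaches size `k`. Folds and
#' classifier randomness are pinned by `seed`, and AUC ties are broken by
#' feature name, so the path is deterministic and nested: the subset of size
#' `k` always contains the subset of size `k - 1`.
#'
#' @param X data.frame of numeric features.
#' @param y binary labels.
#' @param spec a [classifier_spec()] used for the inner scoring.
#' @param k target subset size, `1 <= k <= ncol(X)`.
#' @param n_folds stratified folds for the inner AUC.
#' @param seed integer seed.
#' @param cache optional environment from a previous call with the same
#'   `(X, y, spec, n_folds, seed)`; the computed path is reused and extended,
#'   so evaluating several `k` values costs one path.
#' @return list with `subset` (ordered character vector of length `k`),
#'   `auc` (inner CV AUC at size `k`), `path` (data.frame `feature, auc` per
#'   step) and `cache` (the environment, for reuse).
#' @export
sfs <- function(X, y, spec, k, n_folds = 5L, seed = 1L, cache = NULL) {
  check_feature_table(X)
  y <- as_binary_factor(y)
  p <- ncol(X)
  if (k < 1L || k > p) {
    stop("k must lie in [1, ", p, "], got ", k, call. = FALSE)
  }
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    cache$order <- character(0)
    cache$auc <- numeric(0)
  }
  while (length(cache$order) < k) {
    candidates <- sort(setdiff(names(X), cache$order))
    scores <- vapply(candidates, function(f) {
      cv_auc(X[, c(cache$order, f), drop = FALSE], y, spec,
             n_folds = n_folds, seed = seed)$mean
    }, numeric(1))
    best <- candidates[which.max(scores)]  # ties: first in sorted order
    cache$order <- c(cache$order, best)
    cache$auc <- c(cache$auc, max(scores))
  }
  list(subset = cache$order[seq_len(k)], auc = cache$auc[k],
       path = data.frame(feature = cache$order, auc = cache$auc,
                         stringsAsFactors = FALSE),
       cache = cache)
}

#' Stage C search space
#'
#' Convenience constructor for the joint space over the SFS subset size and
#' the classifier hyperparameters.
#'
#' @param kind `"rf"` or `"svm"`.
#' @param k_range integer range for the number of selected features.
#' @param tune named list of additional hyperparameter dimensions (see
#'   [dim_integer()], [dim_numeric()], [dim_categorical()]); names must match
#'   [classifier_spec()] arguments. Empty list = classifier fixed at
#'   `fixed`/defaults.
#' @param fixed named list of fixed classifier hyperparameters.
#' @param budget,n_init,seed passed to [search_space()].
#' @return a [search_space()] with attributes `kind` and `fixed`.
#' @export
stage_c_space <- function(kind = c("rf", "svm"), k_range,
                          tune = list(), fixed = list(),
                          budget = 50L, n_init = 10L, seed = 1L) {
  kind <- match.arg(kind)
  dims <- c(list(k = dim_integer(k_range[1], k_range[2])), tune)
  sp <- do.call(search_space, c(dims, list(budget = budget, n_init = n_init,
                                           seed = seed)))
  attr(sp, "kind") <- kind
  attr(sp, "fixed") <- fixed
  sp
}

config_to_spec <- function(space, cfg) {
  fixed <- attr(space, "fixed") %||% list()
  pars <- c(list(kind = attr(space, "kind")), fixed,
            cfg[setdiff(names(cfg), c("k", names(fixed)))])
  do.call(classifier_spec, pars)
}

#' Stage C: sequential selection tuned by Bayesian optimization
#'
#' Runs [bayes_opt_tune()] over the joint space of subset size `k` and
#' classifier hyperparameters; each trial evaluates the [sfs()] subset of the
#' proposed size with the proposed classifier, scored by inner
#' cross-validated AUC. SFS paths are cached per classifier configuration, so
#' trials differing only in `k` reuse the greedy path. The final feature set
#' is the best trial's subset.
#'
#' @param X data.frame of numeric features (typically the Stage B survivors).
#' @param y binary labels.
#' @param space a [stage_c_space()]; its `k` range must fit within `ncol(X)`.
#' @param n_folds inner CV folds.
#' @param seed integer seed (folds + classifier randomness; the optimizer
#'   uses the space's own seed).
#' @return list with `selected` (N_f features), `best_spec` (tuned
#'   [classifier_spec()]), `best_k`, `cv_auc`, `trials` (trial log) and
#'   `trace` (`sfs_not_selected` events for dropped features).
#' @export
stage_c <- function(X, y, space, n_folds = 5L, seed = 1L) {
  check_feature_table(X)
  y <- as_binary_factor(y)
  kdim <- space$dims$k
  if (is.null(kdim)) stop("space must contain an integer dimension 'k'", call. = FALSE)
  if (kdim$upper > ncol(X)) {
    stop("k range exceeds available features (", ncol(X), ")", call. = FALSE)
  }
  caches <- new.env(parent = emptyenv())
  objective <- function(cfg) {
    spec <- config_to_spec(space, cfg)
    key <- spec_key(spec)
    cache <- caches[[key]]
    res <- sfs(X, y, spec, k = cfg$k, n_folds = n_folds, seed = seed,
               cache = cache)
    caches[[key]] <- res$cache
    res$auc
  }
  opt <- bayes_opt_tune(objective, space)
  best_spec <- config_to_spec(space, opt$best_config)
  best <- sfs(X, y, best_spec, k = opt$best_config$k, n_folds = n_folds,
              seed = seed, cache = caches[[spec_key(best_spec)]])
  dropped <- setdiff(names(X), best$subset)
  trace <- if (length(dropped)) {
    trace_event(dropped, "stage_c", "sfs_not_selected", NA_real_)
  } else new_trace()
  list(selected = best$subset, best_spec = best_spec,
       best_k = opt$best_config$k, cv_auc = best$auc,
       trials = opt$trials, trace = trace)
}
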