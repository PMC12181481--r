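#' Stage A configuration
#'
#' @param alpha mutual-information threshold in nats (features with MI below
#'   `alpha` are dropped). `alpha = 0` keeps everything.
#' @param beta absolute Pearson correlation threshold in `(0, 1]` for the
#'   redundancy pruning pass.
#' @param mi_estimator `"knn"` or `"discrete"` (see [mutual_information()]).
#' @param k neighbors for the knn MI estimator.
#' @param bins bins for the discrete MI estimator on continuous features.
#' @param seed seed for the knn estimator's tie-breaking jitter.
#' @return object of class `stage_a_config`.
#' @export
stage_a_config <- function(alpha = 0.01, beta = 0.8,
                           mi_estimator = c("knn", "discrete"),
                           k = 3L, bins = 10L, seed = 0L) {
  mi_estimator <- match.arg(mi_estimator)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, mi_estimator = mi_estimator,
                 k = as.integer(k), bins = as.integer(bins),
                 seed = as.integer(seed)),
            class = "stage_a_config")
}

new_trace <- function() {
  data.frame(feature = character(0), stage = character(0), rule = character(0),
             statistic = numeric(0), partner = character(0),
             stringsAsFactors = FALSE)
}

trace_event <- function(feature, stage, rule, statistic, partner = NA_character_) {
  data.frame(feature = feature, stage = stage, rule = rule,
             statistic = statistic, partner = partner, stringsAsFactors = FALSE)
}

#' Mutual-information scores for every feature
#'
#' @param X data.frame of numeric features.
#' @param y binary labels.
#' @param config a [stage_a_config()].
#' @return named numeric vector of MI estimates (nats).
#' @export
mi_scores <- function(X, y, config = stage_a_config()) {
  check_feature_table(X)
  vapply(names(X), function(nm) {
    mutual_information(X[[nm]], y, estimator = config$mi_estimator,
                       k = config$k, bins = config$bins, seed = config$seed)
  }, numeric(1))
}

#' Relevance filter: drop features with low mutual information
#'
#' Retains features whose MI with the class label is at least `alpha`.
#'
#' @param X data.frame of numeric features.
#' @param y binary labels.
#' @param alpha MI threshold in nats.
#' @param mi optional precomputed named MI vector (else computed via `config`).
#' @param config a [stage_a_config()].
#' @return list with `X` (retained columns), `trace` (one `mi_below_alpha`
#'   event per dropped feature, with its MI as the statistic) and `mi`.
#' @export
mi_filter <- function(X, y, alpha, mi = NULL, config = stage_a_config(alpha = alpha)) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (is.null(mi)) mi <- mi_scores(X, y, config)
  stopifnot(all(names(X) %in% names(mi)))
  keep <- names(X)[mi[names(X)] >= alpha]
  if (!length(keep)) {
    stop("no feature reaches MI threshold alpha = ", alpha,
         "; largest observed MI is ", signif(max(mi), 4),
         " - use a smaller alpha", call. = FALSE)
  }
  dropped <- setdiff(names(X), keep)
  trace <- if (length(dropped)) {
    trace_event(dropped, "stage_a", "mi_below_alpha", unname(mi[dropped]))
  } else new_trace()
  list(X = X[, keep, drop = FALSE], trace = trace, mi = mi)
}

#' Redundancy pruning by MI-ordered greedy correlation scan
#'
#' Features are sorted by ascending MI (ties broken lexicographically by
#' name). Starting from the lowest-MI feature, each remaining feature is
#' scanned; whenever a pair's absolute Pearson correlation exceeds `beta`,
#' the member with the lower MI is dropped immediately and never
#' reconsidered. The pass repeats on the next surviving feature until no
#' retained pair exceeds `beta`.
#'
#' @param X data.frame of numeric features.
#' @param mi_scores named MI vector covering every column of `X`.
#' @param beta absolute correlation threshold in `(0, 1]`.
#' @return list with `X` (retained columns, original order) and `trace`
#'   (one `correlated_lower_mi` event per dropped feature, statistic = the
#'   offending correlation, partner = the retained higher-MI feature).
#' @export
correlation_prune <- function(X, mi_scores, beta) {
  check_feature_table(X)
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]", call. = FALSE)
  if (!all(names(X) %in% names(mi_scores))) {
    stop("mi_scores must cover every feature", call. = FALSE)
  }
  feats <- names(X)
  mi <- mi_scores[feats]
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance feature(s) (", paste(feats[sds == 0], collapse = ", "),
            "): correlations treated as 0", call. = FALSE)
  }
  R <- suppressWarnings(abs(stats::cor(as.matrix(X))))
  R[!is.finite(R)] <- 0

  ord <- feats[order(mi, feats)]  # ascending MI, lexicographic tie-break
  alive <- stats::setNames(rep(TRUE, length(feats)), feats)
  events <- list()
  i <- 1L
  while (i <= length(ord)) {
    cur <- ord[i]
    if (alive[cur]) {
      for (j in seq_along(ord)) {
        if (j == i) next
        other <- ord[j]
        if (!alive[other]) next
        r <- R[cur, other]
        if (r > beta) {
          # ascending order makes `cur` the minimum-MI live feature, so the
          # lower-MI member is `cur` (ties resolved by the sort order)
          if (mi[cur] <= mi[other]) {
            alive[cur] <- FALSE
            events[[length(events) + 1L]] <-
              trace_event(cur, "stage_a", "correlated_lower_mi", r, other)
            break
          } else {
            alive[other] <- FALSE
            events[[length(events) + 1L]] <-
              trace_event(other, "stage_a", "correlated_lower_mi", r, cur)
          }
        }
      }
    }
    i <- i + 1L
  }
  trace <- if (length(events)) do.call(rbind, events) else new_trace()
  list(X = X[, feats[alive[feats]], drop = FALSE], trace = trace)
}

#' Stage A: relevance filtering then redundancy pruning
#'
#' Composition of [mi_filter()] and [correlation_prune()], in that order. The
#' output satisfies: every retained feature has MI >= `alpha`, and no
#' retained pair has absolute Pearson correlation above `beta`.
#'
#' @param X data.frame of numeric features.
#' @param y binary labels.
#' @param config a [stage_a_config()].
#' @return list with `X` (filtered table), `trace` (all drop events in
#'   order) and `mi` (the MI scores of all input features).
#' @export
stage_a <- function(X, y, config = stage_a_config()) {
  f <- mi_filter(X, y, alpha = config$alpha, config = config)
  p <- correlation_prune(f$X, f$mi, beta = config$beta)
  list(X = p$X, trace = rbind(f$trace, p$trace), mi = f$mi)
}
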