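#' Mutual information between a feature and a binary class label
#'
#' Two estimators are provided. `"discrete"` is the plug-in estimator
#' `sum p(x, y) * log(p(x, y) / (p(x) p(y)))` over the empirical joint
#' distribution; it is exact for categorical/integer features (continuous
#' features are first cut into `bins` equal-frequency bins). `"knn"` is the
#' k-nearest-neighbor estimator for a continuous feature against a discrete
#' label (Ross 2014, building on Kraskov et al. 2004): for each point, the
#' distance to its k-th nearest neighbor *within its own class* defines a
#' radius, and the number of neighbors of any class inside that radius enters
#' a digamma-based estimate. A seeded jitter of relative amplitude 1e-10
#' breaks ties, which is the only stochastic element.
#'
#' @param x numeric feature vector.
#' @param y class labels with both classes present (any discrete vector).
#' @param estimator `"knn"` (continuous default) or `"discrete"`.
#' @param k number of neighbors for the knn estimator.
#' @param bins equal-frequency bins used to discretize continuous `x` under
#'   the discrete estimator.
#' @param seed integer seed for the tie-breaking jitter.
#' @return estimated mutual information in nats (clipped at 0).
#' @export
mutual_information <- function(x, y, estimator = c("knn", "discrete"),
                               k = 3L, bins = 10L, seed = 0L) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("y must contain both classes", call. = FALSE)
  }
  if (estimator == "discrete") {
    xd <- if (is.numeric(x) && length(unique(x)) > bins) {
      cut_equal_freq(x, bins)
    } else x
    mi_plugin(xd, y)
  } else {
    mi_knn(x, y, k = k, seed = seed)
  }
}

cut_equal_freq <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

# Plug-in MI from the empirical joint table, in nats. 0 log 0 := 0.
mi_plugin <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  terms <- pxy * log(pxy / outer(px, py))
  max(0, sum(terms[pxy > 0]))
}

# Ross (2014) mixed continuous/discrete estimator. Matches the standard
# construction: within each class, the k-th nearest-neighbor distance (k
# capped at class size - 1) sets a per-point radius just below that distance;
# m_i counts all points (any class, self included) within the radius. Points
# in singleton classes are ignored.
mi_knn <- function(x, y, k = 3L, seed = 0L) {
  x <- as.numeric(x)
  n <- length(x)
  if (stats::sd(x) == 0) return(0)
  set.seed(fan_seed(seed, "mi_knn_jitter"))
  x <- x + stats::rnorm(n, sd = 1e-10 * max(abs(x), 1))

  radius <- numeric(n)
  k_all <- numeric(n)
  lab_count <- numeric(n)
  for (lev in levels(droplevels(y))) {
    idx <- which(y == lev)
    cnt <- length(idx)
    lab_count[idx] <- cnt
    if (cnt > 1L) {
      kk <- min(k, cnt - 1L)
      k_all[idx] <- kk
      d <- kth_nn_dist_1d(x[idx], kk)
      radius[idx] <- d * (1 - 1e-12)
    }
  }
  keep <- lab_count > 1
  xk <- x[keep]; rk <- radius[keep]
  ns <- length(xk)
  xs <- sort(xk)
  m <- findInterval(xk + rk, xs) - findInterval(xk - rk, xs)
  mi <- digamma(ns) + mean(digamma(k_all[keep])) -
    mean(digamma(lab_count[keep])) - mean(digamma(m))
  max(0, mi)
}

# k-th nearest-neighbor distance for every element of a 1-D sample (self
# excluded). Candidates are the k sorted neighbors on each side; the k-th
# smallest of the 2k candidate gaps is extracted by k passes of row minima.
kth_nn_dist_1d <- function(x, k) {
  n <- length(x)
  o <- order(x)
  xo <- x[o]
  cand <- matrix(Inf, n, 2L * k)
  for (s in seq_len(k)) {
    cand[(s + 1):n, s] <- xo[(s + 1):n] - xo[1:(n - s)]
    cand[1:(n - s), k + s] <- xo[(s + 1):n] - xo[1:(n - s)]
  }
  d <- numeric(n)
  for (pass in seq_len(k)) {
    idx <- max.col(-cand, ties.method = "first")
    d <- cand[cbind(seq_len(n), idx)]
    if (pass < k) cand[cbind(seq_len(n), idx)] <- Inf
  }
  out <- numeric(n)
  out[o] <- d
  out
}
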