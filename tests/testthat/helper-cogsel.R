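# Shared fixtures and independent brute-force oracles.

# Small cohort for fast end-to-end tests.
small_cohort <- function(seed = 1, n = 400, ...) {
  generate_cohort(synth_config(
    n_participants = n, n_blocks = 6, block_size = 3,
    n_informative_blocks = 3, n_noise_features = 20, seed = seed, ...
  ))
}

# Binary-labelled feature table from a cohort via the GC pipeline.
cohort_xy <- function(cohort) {
  lab <- gc_pipeline(cohort$battery)
  keep <- match(lab$retained, cohort$features$participant_id)
  list(X = cohort$features[keep, -1, drop = FALSE], y = lab$y,
       truth = cohort$truth, gc = lab)
}

# Plug-in MI oracle by direct summation over the joint table (nats).
oracle_mi_plugin <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pxy <- tab[i, j] / n
      if (pxy > 0) {
        s <- s + pxy * log(pxy / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
      }
    }
  }
  s
}

# All-pairs Mann-Whitney AUC oracle (ties count 1/2).
oracle_auc_pairs <- function(y, scores, positive) {
  pos <- scores[y == positive]
  neg <- scores[y != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Brute-force confusion tally.
oracle_confusion_metrics <- function(y_true, y_pred, positive) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y_true)) {
    t_pos <- y_true[i] == positive
    p_pos <- y_pred[i] == positive
    if (p_pos && t_pos) tp <- tp + 1
    else if (p_pos && !t_pos) fp <- fp + 1
    else if (!p_pos && t_pos) fn <- fn + 1
    else tn <- tn + 1
  }
  c(accuracy = 100 * (tp + tn) / length(y_true),
    precision = 100 * if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = 100 * if (tp + fn > 0) tp / (tp + fn) else 0)
}

# Exhaustive stage-A postcondition check: every retained pair within beta,
# every drop recorded exactly once with a valid cause/partner.
oracle_check_stage_a <- function(X_in, result, beta, mi) {
  Xo <- result$X
  R <- suppressWarnings(abs(stats::cor(as.matrix(Xo))))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  ok_pairs <- all(R <= beta + 1e-12)
  dropped <- setdiff(names(X_in), names(Xo))
  tr <- result$trace
  ok_partition <- setequal(tr$feature, dropped) && !anyDuplicated(tr$feature)
  ok_partner <- all(vapply(seq_len(nrow(tr)), function(i) {
    if (tr$rule[i] != "correlated_lower_mi") return(TRUE)
    p <- tr$partner[i]
    !is.na(p) && mi[p] >= mi[tr$feature[i]]
  }, logical(1)))
  list(ok = ok_pairs && ok_partition && ok_partner,
       pairs = ok_pairs, partition = ok_partition, partner = ok_partner)
}

# Correlated random instance for stage-A stress tests.
random_instance <- function(seed, n = 200, p_max = 50) {
  set.seed(seed)
  n_blocks <- sample(3:6, 1)
  bs <- sample(2:4, 1)
  p_noise <- sample(5:15, 1)
  p_dup <- sample(0:4, 1)
  z <- stats::rnorm(n)
  y <- factor(ifelse(z + stats::rnorm(n) > 0, "PositiveAger", "CognitiveDecliner"))
  cols <- list()
  for (b in seq_len(n_blocks)) {
    f <- stats::rnorm(n)
    for (j in seq_len(bs)) {
      cols[[sprintf("b%02d_%d", b, j)]] <-
        sqrt(0.85) * f + sqrt(0.15) * stats::rnorm(n) + 0.3 * z * (b <= 2)
    }
  }
  for (i in seq_len(p_noise)) cols[[sprintf("n%02d", i)]] <- stats::rnorm(n)
  nm <- names(cols)
  for (i in seq_len(p_dup)) {
    src <- cols[[sample(nm, 1)]]
    cols[[sprintf("d%02d", i)]] <- 0.98 * src + 0.05 * stats::rnorm(n)
  }
  list(X = as.data.frame(cols)[seq_len(min(length(cols), p_max))], y = y)
}
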