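#' Pipeline configuration for the full multi-stage selector
#'
#' Bundles the per-stage configurations with the Stage C search space
#' parameters. The defaults are sized for cohorts of a few thousand
#' participants with a few hundred features: a mild MI threshold, redundancy
#' pruning at |r| > 0.8, the default 25-point C grid with epsilon = 0.005,
#' and a Stage C search over 4-16 features with a fixed moderately sized
#' forest and a small optimization budget.
#'
#' @param stage_a a [stage_a_config()].
#' @param stage_b a [stage_b_config()].
#' @param kind final classifier kind, `"rf"` or `"svm"`.
#' @param k_range Stage C subset-size range (clipped to the Stage B output).
#' @param tune named list of extra classifier dimensions for the Stage C
#'   space (empty = classifier fixed at `fixed`).
#' @param fixed fixed classifier hyperparameters for Stage C and the final
#'   fit.
#' @param budget,n_init Bayesian-optimization budget.
#' @param n_folds CV folds shared by stages B and C.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stage_a = stage_a_config(alpha = 0.01, beta = 0.8),
                            stage_b = stage_b_config(),
                            kind = c("rf", "svm"),
                            k_range = c(4L, 16L),
                            tune = list(),
                            fixed = list(num.trees = 150L, min.node.size = 5L),
                            budget = 8L, n_init = 4L, n_folds = 5L) {
  kind <- match.arg(kind)
  structure(list(stage_a = stage_a, stage_b = stage_b, kind = kind,
                 k_range = k_range, tune = tune, fixed = fixed,
                 budget = as.integer(budget), n_init = as.integer(n_init),
                 n_folds = as.integer(n_folds)),
            class = "pipeline_config")
}

#' Multi-stage feature selection (Stages A, B, C)
#'
#' Runs the full chain on a training table: mutual-information filtering and
#' correlation pruning, the L1 path with the smallest-adequate-C rule, then
#' sequential forward selection with subset size and classifier
#' hyperparameters tuned jointly by Bayesian optimization. By construction
#' the final set is nested: selected (Stage C) is a subset of the Stage B
#' survivors, which are a subset of the Stage A survivors.
#'
#' @param X training feature table (data.frame).
#' @param y training labels.
#' @param config a [pipeline_config()].
#' @param seed integer top-level seed.
#' @return list with `selected`, `best_spec`, `stage_a` / `stage_b` /
#'   `stage_c` results, and the combined `trace` recording every dropped
#'   feature with its triggering rule.
#' @export
multistage_select <- function(X, y, config = pipeline_config(), seed = 1L) {
  y <- as_binary_factor(y)
  A <- stage_a(X, y, config$stage_a)
  B <- stage_b(A$X, y, config$stage_b, seed = fan_seed(seed, "pipe_b"))
  XB <- A$X[, B$selected, drop = FALSE]
  kr <- c(min(config$k_range[1], ncol(XB)), min(config$k_range[2], ncol(XB)))
  space <- stage_c_space(config$kind, kr, tune = config$tune,
                         fixed = config$fixed,
                         budget = config$budget, n_init = config$n_init,
                         seed = fan_seed(seed, "pipe_c_space"))
  C <- stage_c(XB, y, space, n_folds = config$n_folds,
               seed = fan_seed(seed, "pipe_c"))
  list(selected = C$selected, best_spec = C$best_spec,
       stage_a = A, stage_b = B, stage_c = C,
       trace = rbind(A$trace, B$trace, C$trace))
}

#' End-to-end synthetic study
#'
#' Generates a cohort, derives the binary cognitive classes through the GC
#' pipeline, splits off a stratified test set, runs the multi-stage selector
#' on the training rows only, fits the tuned classifier on the final feature
#' set, and reports test metrics, a permuted-label null AUC (the final
#' classifier retrained on shuffled training labels, evaluated on the
#' untouched test set), and the selection's recovery of the planted blocks.
#'
#' @param cohort_config a [synth_config()].
#' @param config a [pipeline_config()].
#' @param seed integer top-level seed (also replaces the cohort seed so one
#'   argument reproduces the study).
#' @param test_fraction held-out fraction.
#' @param n_perm permuted-label refits for the null AUC.
#' @return list with `selected`, `metrics` (percent), `null_auc` (percent,
#'   mean over permutations), `recovery` ([score_selection()] output),
#'   `sizes` (feature counts per stage), `fit`, `gc`, `cohort`, `split`.
#' @export
run_study <- function(cohort_config = synth_config(),
                      config = pipeline_config(),
                      seed = 1L, test_fraction = 0.2, n_perm = 1L) {
  cohort_config$seed <- fan_seed(seed, "cohort")
  cohort <- generate_cohort(cohort_config)
  lab <- gc_pipeline(cohort$battery)
  keep <- match(lab$retained, cohort$features$participant_id)
  X <- cohort$features[keep, -1, drop = FALSE]
  y <- lab$y

  sp <- split_cohort(X, y, test_fraction, seed = fan_seed(seed, "study_split"))
  sel <- multistage_select(sp$train$X, sp$train$y, config,
                           seed = fan_seed(seed, "study_select"))

  fit <- fit_classifier(sel$best_spec,
                        sp$train$X[, sel$selected, drop = FALSE],
                        sp$train$y, seed = fan_seed(seed, "study_fit"))
  metrics <- evaluate_classifier(fit, sp$test$X[, sel$selected, drop = FALSE],
                                 sp$test$y)

  null_auc <- vapply(seq_len(n_perm), function(i) {
    set.seed(fan_seed(seed, paste0("perm", i)))
    y_perm <- sample(sp$train$y)
    nfit <- fit_classifier(sel$best_spec,
                           sp$train$X[, sel$selected, drop = FALSE],
                           y_perm, seed = fan_seed(seed, paste0("permfit", i)))
    100 * auc_score(sp$test$y, predict_scores(nfit, sp$test$X[, sel$selected, drop = FALSE]))
  }, numeric(1))

  list(
    selected = sel$selected,
    metrics = metrics,
    null_auc = mean(null_auc),
    recovery = score_selection(sel$selected, cohort$truth),
    sizes = c(input = ncol(X),
              stage_a = ncol(sel$stage_a$X),
              stage_b = length(sel$stage_b$selected),
              final = length(sel$selected)),
    selection = sel, fit = fit, gc = lab, cohort = cohort, split = sp
  )
}
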