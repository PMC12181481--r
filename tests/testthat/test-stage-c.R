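sfs_fixture <- function(seed = 1, n = 120) {
  set.seed(seed)
  y <- rep(c("CognitiveDecliner", "PositiveAger"), each = n / 2)
  yb <- as.integer(y == "PositiveAger")
  X <- data.frame(
    copy = yb + 0.01 * rnorm(n),
    weak = 0.5 * yb + rnorm(n),
    junk = rnorm(n)
  )
  list(X = X, y = y)
}

test_that("forward selection is greedy, nested and exact on hand cases", {
  fx <- sfs_fixture()
  spec <- classifier_spec("rf", num.trees = 100)
  # k = 1 picks what an exhaustive single-feature search picks
  s1 <- sfs(fx$X, fx$y, spec, k = 1, n_folds = 4, seed = 2)
  exhaustive <- vapply(names(fx$X), function(f) {
    cv_auc(fx$X[, f, drop = FALSE], fx$y, spec, n_folds = 4, seed = 2)$mean
  }, numeric(1))
  expect_equal(s1$subset, names(which.max(exhaustive)))
  expect_equal(s1$subset, "copy")
  # greedy growth never drops: subsets are nested, inner AUC non-decreasing
  s2 <- sfs(fx$X, fx$y, spec, k = 2, n_folds = 4, seed = 2)
  s3 <- sfs(fx$X, fx$y, spec, k = 3, n_folds = 4, seed = 2)
  expect_equal(s2$subset[1], s1$subset)
  expect_equal(s3$subset[1:2], s2$subset)
  expect_gte(s2$auc, s1$auc - 1e-12)
  # k = p returns every feature
  expect_setequal(s3$subset, names(fx$X))
  expect_error(sfs(fx$X, fx$y, spec, k = 9), "k must lie")
})

test_that("the SFS cache reproduces the uncached path", {
  fx <- sfs_fixture(seed = 5)
  spec <- classifier_spec("rf", num.trees = 80)
  full <- sfs(fx$X, fx$y, spec, k = 3, n_folds = 3, seed = 7)
  step1 <- sfs(fx$X, fx$y, spec, k = 1, n_folds = 3, seed = 7)
  step3 <- sfs(fx$X, fx$y, spec, k = 3, n_folds = 3, seed = 7,
               cache = step1$cache)
  expect_identical(full$subset, step3$subset)
  expect_identical(full$path, step3$path)
})

test_that("Bayesian optimization honours its budget, seed and exhaustiveness", {
  # budget 1 returns the single evaluated config
  o1 <- bayes_opt_tune(function(cfg) cfg$x,
                       search_space(x = dim_integer(1, 5), budget = 1, seed = 3))
  expect_equal(nrow(o1$trials), 1)
  expect_equal(o1$best_value, o1$trials$value[1])
  # deterministic objective with a unique maximum over 5 values, budget 5,
  # non-repeating proposals: the maximum is always found
  obj <- function(cfg) -(cfg$x - 4)^2
  o5 <- bayes_opt_tune(obj, search_space(x = dim_integer(1, 5),
                                         budget = 5, n_init = 2, seed = 11))
  expect_equal(o5$best_config$x, 4)
  expect_equal(sort(o5$trials$x), 1:5)  # exhaustive, no repeats
  # identical space/seed/budget: identical trial log
  o5b <- bayes_opt_tune(obj, search_space(x = dim_integer(1, 5),
                                          budget = 5, n_init = 2, seed = 11))
  expect_identical(o5$trials, o5b$trials)
  # best-trial objective dominates every logged trial
  expect_true(all(o5$trials$value <= o5$best_value))
})

test_that("optimizer surfaces a total objective failure with its log", {
  expect_error(
    bayes_opt_tune(function(cfg) stop("boom"),
                   search_space(x = dim_integer(1, 3), budget = 2, seed = 1)),
    "every trial"
  )
})

test_that("mixed spaces with numeric and categorical dimensions work", {
  obj <- function(cfg) -abs(log10(cfg$cost)) - (cfg$kind2 == "b")
  sp <- search_space(cost = dim_numeric(1e-2, 1e2, log = TRUE),
                     kind2 = dim_categorical(c("a", "b")),
                     budget = 12, n_init = 5, seed = 2)
  o <- bayes_opt_tune(obj, sp)
  expect_equal(o$best_config$kind2, "a")
  expect_lt(abs(log10(o$best_config$cost)), 1.5)
})

test_that("stage C returns the best trial's subset and a complete trace", {
  fx <- sfs_fixture(seed = 9, n = 100)
  sp <- stage_c_space("rf", c(1, 3), fixed = list(num.trees = 80L),
                      budget = 3, n_init = 2, seed = 21)
  res <- stage_c(fx$X, fx$y, sp, n_folds = 3, seed = 5)
  expect_true(all(res$selected %in% names(fx$X)))
  expect_equal(length(res$selected), res$best_k)
  expect_setequal(c(res$selected, res$trace$feature), names(fx$X))
  expect_equal(nrow(res$trials), 3)
  # restricting the space to k = p returns the full input set
  sp_all <- stage_c_space("rf", c(3, 3), fixed = list(num.trees = 80L),
                          budget = 1, seed = 2)
  res_all <- stage_c(fx$X, fx$y, sp_all, n_folds = 3, seed = 5)
  expect_setequal(res_all$selected, names(fx$X))
  expect_error(stage_c(fx$X, fx$y,
                       stage_c_space("rf", c(1, 10), budget = 1, seed = 1)),
               "k range exceeds")
})

test_that("the full chain is nested and beats chance-level block recovery", {
  obs <- null <- numeric(0)
  for (s in c(23, 24, 25)) {
    co <- generate_cohort(synth_config(
      n_participants = 600, n_blocks = 10, block_size = 3,
      n_informative_blocks = 5, n_noise_features = 30, seed = s
    ))
    xy <- cohort_xy(co)
    sel <- multistage_select(
      xy$X, xy$y,
      pipeline_config(stage_a = stage_a_config(alpha = 0, beta = 0.8),
                      stage_b = stage_b_config(C_grid = 10^seq(-3, 2, length.out = 10)),
                      k_range = c(2L, 6L), budget = 4L, n_init = 2L,
                      n_folds = 3L),
      seed = s
    )
    # subset chain: final within stage B within stage A
    expect_true(all(sel$selected %in% sel$stage_b$selected))
    expect_true(all(sel$stage_b$selected %in% names(sel$stage_a$X)))
    expect_lte(length(sel$selected), length(sel$stage_b$selected))
    obs <- c(obs, score_selection(sel$selected, co$truth)$block_recall)
    # chance baseline: equal-size random draws from the feature pool
    set.seed(s + 1000)
    null <- c(null, vapply(1:20, function(i) {
      draw <- sample(names(co$truth$feature_to_block), length(sel$selected))
      score_selection(draw, co$truth)$block_recall
    }, numeric(1)))
  }
  expect_gte(mean(obs), mean(null))
})
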