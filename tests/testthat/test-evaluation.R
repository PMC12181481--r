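# Mock classifier whose scores come from a plain function: lets partial
# dependence be checked against exactly controllable response surfaces.
mock_fit <- function(f) structure(list(f = f), class = "mock_fit")
predict_scores.mock_fit <- function(fit, X) fit$f(X)
registerS3method("predict_scores", "mock_fit", predict_scores.mock_fit,
                 envir = asNamespace("cogsel"))

test_that("stratified split preserves sizes, proportions and determinism", {
  set.seed(1)
  X <- data.frame(a = rnorm(100))
  y <- rep(c("CognitiveDecliner", "PositiveAger"), c(40, 60))
  sp <- split_cohort(X, y, 0.2, seed = 5)
  expect_equal(nrow(sp$test$X), 20)
  expect_equal(nrow(sp$train$X), 80)
  expect_lte(abs(sum(sp$test$y == "PositiveAger") - 12), 1)
  sp2 <- split_cohort(X, y, 0.2, seed = 5)
  expect_identical(sp$test$idx, sp2$test$idx)
  expect_error(split_cohort(X, y, 1.2, seed = 1), "test_fraction")
  expect_error(split_cohort(X[1:3, , drop = FALSE], y[c(1, 1, 41)], 0.2, 1),
               "at least 2")
})

test_that("metrics match hand values and the brute-force confusion oracle", {
  y <- factor(rep(c("CognitiveDecliner", "PositiveAger"), each = 10),
              levels = c("CognitiveDecliner", "PositiveAger"))
  # perfect classifier
  m <- classification_metrics(y, y, c(rep(0, 10), rep(1, 10)))
  expect_equal(unname(m), c(100, 100, 100, 100))
  # all-positive on a balanced set: recall 100, accuracy 50, precision 50
  all_pos <- factor(rep("PositiveAger", 20), levels = levels(y))
  m2 <- classification_metrics(y, all_pos, rep(0.9, 20))
  expect_equal(m2[["recall"]], 100)
  expect_equal(m2[["accuracy"]], 50)
  expect_equal(m2[["precision"]], 50)
  # random predictions against the independent tally
  set.seed(7)
  for (i in 1:5) {
    y_pred <- factor(sample(levels(y), 20, replace = TRUE), levels = levels(y))
    scores <- runif(20)
    m3 <- classification_metrics(y, y_pred, scores)
    oracle <- oracle_confusion_metrics(as.character(y), as.character(y_pred),
                                       "PositiveAger")
    expect_equal(m3[c("accuracy", "precision", "recall")], oracle)
  }
  expect_error(classification_metrics(y[1:10], all_pos[1:10], rep(1, 10)),
               "two observed classes")
})

test_that("AUC equals the all-pairs Mann-Whitney statistic on small samples", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    y <- factor(sample(c("CognitiveDecliner", "PositiveAger"), n, replace = TRUE,
                       prob = c(0.5, 0.5)),
                levels = c("CognitiveDecliner", "PositiveAger"))
    if (nlevels(droplevels(y)) < 2) next
    scores <- round(runif(n), 2)  # coarse grid to exercise ties
    m <- classification_metrics(y, y, scores)
    expect_equal(m[["auc"]] / 100,
                 oracle_auc_pairs(as.character(y), scores, "PositiveAger"),
                 tolerance = 1e-12)
  }
})

test_that("random scores on a large balanced set give chance AUC", {
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    y <- rep(c("CognitiveDecliner", "PositiveAger"), each = 1000)
    classification_metrics(factor(y), factor(y), rnorm(2000))[["auc"]]
  }, numeric(1))
  expect_true(all(aucs >= 45 & aucs <= 55))
})

test_that("importance ranking is normalized, sorted and annotated", {
  co <- small_cohort(seed = 3)
  xy <- cohort_xy(co)
  keep <- c("smri_b01_f1", "smri_b02_f1", "noise_001")
  fit <- fit_classifier(classifier_spec("rf", num.trees = 150),
                        xy$X[, keep], xy$y, seed = 1)
  imp <- importance_ranking(fit, meta = co$meta, top_k = 3)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$importance) <= 0))
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$visit[imp$feature == "smri_b01_f1"], "III")
  # a single-feature forest puts all weight on that feature
  fit1 <- fit_classifier(classifier_spec("rf", num.trees = 50),
                         xy$X[, "smri_b01_f1", drop = FALSE], xy$y, seed = 1)
  imp1 <- importance_ranking(fit1, top_k = 5)
  expect_equal(imp1$importance, 1)
  expect_error(importance_ranking(fit_classifier(classifier_spec("svm"),
                                                 xy$X[, keep], xy$y)),
               "random forest")
})

test_that("planted informative features outrank pure noise in the forest", {
  ranks <- vapply(1:5, function(s) {
    co <- small_cohort(seed = s + 40)
    xy <- cohort_xy(co)
    inf <- names(xy$X)[grepl("^smri_b0[1-3]_", names(xy$X))]
    noise <- names(xy$X)[grepl("^noise_", names(xy$X))][1:5]
    fit <- fit_classifier(classifier_spec("rf", num.trees = 200),
                          xy$X[, c(inf, noise)], xy$y, seed = s)
    imp <- importance_ranking(fit, top_k = length(c(inf, noise)))
    median(match(noise, imp$feature)) - median(match(inf, imp$feature))
  }, numeric(1))
  expect_gt(median(ranks), 0)
})

test_that("partial dependence reproduces controlled response surfaces", {
  X <- data.frame(a = seq(-2, 2, length.out = 50), b = rnorm(50))
  # model ignoring the feature: flat curve
  pd_flat <- partial_dependence(mock_fit(function(X) rep(0.4, nrow(X))), X, "a")
  expect_true(all(pd_flat$prob == 0.4))
  # threshold model: step at the cut
  pd_step <- partial_dependence(mock_fit(function(X) as.numeric(X$a > 0.5)),
                                X, "a", grid_size = 41)
  expect_true(all(pd_step$prob[pd_step$value <= 0.5] == 0))
  expect_true(all(pd_step$prob[pd_step$value > 0.5] == 1))
  # constant feature: single-point curve with a warning
  Xc <- data.frame(a = rep(1, 10), b = rnorm(10))
  expect_warning(pd1 <- partial_dependence(mock_fit(function(X) X$b), Xc, "a"),
                 "constant")
  expect_equal(nrow(pd1), 1)
  expect_error(partial_dependence(mock_fit(identity), X, "zz"), "not in table")
})

test_that("partial dependence of a planted feature trends upward", {
  rhos <- vapply(1:5, function(s) {
    co <- small_cohort(seed = s + 60, n = 300)
    xy <- cohort_xy(co)
    keep <- c("smri_b01_f1", "noise_001", "noise_002")
    fit <- fit_classifier(classifier_spec("rf", num.trees = 200),
                          xy$X[, keep], xy$y, seed = s)
    pd <- partial_dependence(fit, xy$X[, keep], "smri_b01_f1", grid_size = 15)
    cor(pd$value, pd$prob, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos >= 0))
})

test_that("selection never reads the test partition", {
  co <- small_cohort(seed = 71, n = 300)
  xy <- cohort_xy(co)
  sp <- split_cohort(xy$X, xy$y, 0.2, seed = 3)
  cfg <- pipeline_config(stage_a = stage_a_config(alpha = 0, beta = 0.8),
                         stage_b = stage_b_config(C_grid = 10^seq(-2, 2, length.out = 6)),
                         k_range = c(2L, 4L), budget = 3L, n_init = 2L, n_folds = 3L)
  sel1 <- multistage_select(sp$train$X, sp$train$y, cfg, seed = 11)
  # mutate every test row; the training-side selection must be unchanged
  sp$test$X[] <- sp$test$X[] * 10 + 99
  sel2 <- multistage_select(sp$train$X, sp$train$y, cfg, seed = 11)
  expect_identical(sel1$selected, sel2$selected)
  expect_identical(sel1$best_spec, sel2$best_spec)
})

test_that("the benchmark grid has six coherent rows", {
  co <- small_cohort(seed = 83, n = 300)
  xy <- cohort_xy(co)
  cfg <- benchmark_config(
    stage_a = stage_a_config(alpha = 0, beta = 0.8),
    stage_b = stage_b_config(C_grid = 10^seq(-2, 2, length.out = 6), n_folds = 3),
    k_range = c(2L, 4L), budget = 3L, n_init = 2L, n_folds = 3L
  )
  rep <- run_benchmark(xy$X, xy$y, cfg, seed = 7)
  expect_s3_class(rep, "benchmark_report")
  expect_equal(nrow(rep), 6)
  expect_setequal(unique(rep$classifier), c("RF", "SVM"))
  expect_setequal(unique(rep$selector), c("L1", "SFS", "L1+SFS"))
  metrics <- as.matrix(rep[, c("accuracy", "precision", "recall", "auc")])
  expect_true(all(metrics >= 0 & metrics <= 100))
  expect_true(all(rep$N_f >= 1))
  # the full chain never selects more than the L1 baseline
  for (cl in c("RF", "SVM")) {
    expect_lte(rep$N_f[rep$classifier == cl & rep$selector == "L1+SFS"],
               rep$N_f[rep$classifier == cl & rep$selector == "L1"])
  }
})
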