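test_that("identical config and seed give byte-identical cohorts", {
  cfg <- synth_config(n_participants = 100, n_blocks = 4, block_size = 2,
                      n_informative_blocks = 2, n_noise_features = 10, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
})

test_that("cohort dimensions, metadata and ground truth are consistent", {
  cfg <- synth_config(n_participants = 150, n_blocks = 5, block_size = 3,
                      n_informative_blocks = 2, n_noise_features = 12, seed = 7)
  co <- generate_cohort(cfg)
  p_block <- cfg$n_blocks * cfg$block_size
  feats <- setdiff(names(co$features), "participant_id")
  expect_equal(sum(grepl("^smri_b", feats)), p_block)
  expect_equal(sum(grepl("^(noise|dup)_", feats)), cfg$n_noise_features)
  # every emitted feature appears in the truth map and in the metadata
  expect_setequal(feats, names(co$truth$feature_to_block))
  expect_setequal(feats, co$meta$feature)
  expect_length(co$truth$informative_block_ids, cfg$n_informative_blocks)
  blocked <- !is.na(co$truth$feature_to_block)
  expect_equal(sum(blocked), p_block)
  expect_equal(nrow(co$features), 150)
  expect_true(all(co$battery$RT_I > 0 & co$battery$RT_III > 0))
  expect_true(all(co$battery$PM_I %in% 0:1))
  expect_true(all(co$battery$PMM_I >= 0))
  expect_true(all(co$battery$date_III > co$battery$date_I))
})

test_that("invalid configurations name the offending field", {
  expect_error(synth_config(within_block_corr = 1), "within_block_corr")
  expect_error(synth_config(n_informative_blocks = 40, n_blocks = 30),
               "n_informative_blocks")
  expect_error(synth_config(n_participants = 2), "n_participants")
  expect_error(synth_config(test_noise_sd = -1), "test_noise_sd")
})

test_that("noise-free limit: tests are exact functions of the latent trait", {
  co <- generate_cohort(synth_config(
    n_participants = 200, n_blocks = 2, block_size = 2,
    n_informative_blocks = 1, n_noise_features = 4,
    test_noise_sd = 0, effect_size = 0, seed = 3
  ))
  z <- unname(co$truth$latent_trait)
  # drift makes visit III latent affine in z too, so check visit I exactly
  for (col in c("FI_I")) {
    fit <- lm(co$battery[[col]] ~ z)
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }
  fit_rt <- lm(log(co$battery$RT_I) ~ z)
  expect_lt(max(abs(residuals(fit_rt))), 1e-9)
  fit_pmm <- lm(log1p(co$battery$PMM_I) ~ z)
  expect_lt(max(abs(residuals(fit_pmm))), 1e-9)
  # PM is binary by contract: at zero noise it is a deterministic threshold
  expect_true(all(co$battery$PM_I == as.integer(2.17 + 1.35 * z > 0)))
  # directions: higher latent = better FI, faster RT, fewer errors
  expect_gt(coef(fit)[2], 0)
  expect_lt(coef(fit_rt)[2], 0)
  expect_lt(coef(fit_pmm)[2], 0)
})

test_that("within-block correlation converges to the configured value", {
  mean_block_r <- function(n, seed) {
    co <- generate_cohort(synth_config(
      n_participants = n, n_blocks = 8, block_size = 3,
      n_informative_blocks = 0, n_noise_features = 0,
      within_block_corr = 0.9, seed = seed
    ))
    rs <- vapply(sprintf("B%02d", 1:8), function(b) {
      f <- names(co$truth$feature_to_block)[
        !is.na(co$truth$feature_to_block) & co$truth$feature_to_block == b]
      R <- stats::cor(co$features[, f])
      mean(R[upper.tri(R)])
    }, numeric(1))
    mean(rs)
  }
  r5000 <- mean_block_r(5000, 21)
  r500 <- mean_block_r(500, 22)
  expect_gt(r5000, 0.85)
  expect_lt(r5000, 0.95)
  expect_lt(abs(r5000 - 0.9), abs(r500 - 0.9) + 0.02)
  expect_lt(abs(r5000 - 0.9), 0.01)
})

test_that("informative features separate the latent-extreme groups at the configured effect size", {
  co <- generate_cohort(synth_config(
    n_participants = 8000, n_blocks = 6, block_size = 3,
    n_informative_blocks = 3, n_noise_features = 0,
    effect_size = 0.5, test_noise_sd = 0, seed = 19
  ))
  z <- unname(co$truth$latent_trait)
  q <- quantile(z, c(0.25, 0.75))
  top <- z > q[2]; bot <- z < q[1]
  x <- co$features$smri_b01_f1
  smd <- (mean(x[top]) - mean(x[bot])) / sd(x)
  expect_lt(abs(smd - 0.5), 0.08)
})

test_that("score_selection matches its definition", {
  truth <- list(
    informative_block_ids = c("A", "B"),
    feature_to_block = c(a1 = "A", a2 = "A", b1 = "B", noise7 = NA_character_),
    latent_trait = NULL
  )
  expect_equal(score_selection(c("a1", "b1"), truth),
               list(block_recall = 1.0, false_positive_count = 0L))
  expect_equal(score_selection(character(0), truth),
               list(block_recall = 0.0, false_positive_count = 0L))
  # per the definition, {a1, a2} covers block A only: recall 1/2
  expect_equal(score_selection(c("a1", "a2", "noise7"), truth),
               list(block_recall = 0.5, false_positive_count = 1L))
  expect_equal(score_selection(c("a1", "b1", "noise7"), truth),
               list(block_recall = 1.0, false_positive_count = 1L))
  expect_error(score_selection("nope", truth), "unknown feature")
})

test_that("cohort files round-trip through the plain-text writers", {
  co <- small_cohort(seed = 5, n = 60)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  feats <- read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  expect_equal(dim(feats), dim(co$features))
  expect_equal(feats$participant_id, co$features$participant_id)
  meta <- jsonlite::read_json(file.path(dir, "feature_meta.json"))
  expect_setequal(names(meta), co$meta$feature)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_setequal(unlist(gt$informative_block_ids), co$truth$informative_block_ids)
})

test_that("stronger planted effects never reduce an L1 classifier's CV AUC", {
  # majority direction over seeds x adjacent effect-size pairs
  effect_sizes <- c(0.2, 0.5, 0.9)
  auc_of <- function(e, s) {
    co <- generate_cohort(synth_config(
      n_participants = 400, n_blocks = 4, block_size = 2,
      n_informative_blocks = 4, n_noise_features = 0,
      effect_size = e, seed = s
    ))
    xy <- cohort_xy(co)
    path <- l1_auc_path(xy$X[, grepl("^smri", names(xy$X))], xy$y,
                        stage_b_config(C_grid = c(0.5, 1), n_folds = 3), seed = s)
    max(path$mean_auc)
  }
  wins <- 0; total <- 0
  for (s in 1:5) {
    aucs <- vapply(effect_sizes, auc_of, numeric(1), s = s)
    wins <- wins + sum(diff(aucs) >= -0.01)
    total <- total + length(diff(aucs))
  }
  expect_gt(wins / total, 0.5)
})
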