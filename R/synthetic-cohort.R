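#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the selection pipeline is
#' designed for: a participant-by-feature table of continuous morphometry-like
#' measurements organised in highly correlated blocks, a handful of
#' demographic covariates, and a four-test cognitive battery measured at two
#' visits, all driven by a single latent cognition trait. A known subset of
#' blocks is "informative": their features load on the latent trait and hence
#' separate the cognitive classes derived downstream.
#'
#' @param n_participants cohort size (>= 4).
#' @param n_blocks number of correlated feature blocks.
#' @param block_size features per block.
#' @param within_block_corr target pairwise Pearson correlation inside a
#'   block, in `[0, 1)`. Achieved with a single-factor construction
#'   `x = sqrt(rho) * f_block + sqrt(1 - rho) * noise`.
#' @param n_informative_blocks number of blocks whose features carry signal
#'   (`<= n_blocks`).
#' @param effect_size target standardized mean difference of each informative
#'   feature between the bottom- and top-quartile latent groups (the two
#'   classes the labeling pipeline extracts).
#' @param n_noise_features count of additional independent standard-normal
#'   features belonging to no block.
#' @param near_dup_fraction fraction of the noise features generated instead
#'   as near-duplicates (r about 0.97) of randomly chosen informative
#'   features, to stress redundancy pruning.
#' @param test_noise_sd unitless multiplier on the residual noise of every
#'   cognitive test (1 = realistic within-group spread; 0 = noise-free tests
#'   that are exact functions of the latent trait).
#' @param visit_gap_years nominal years between visit I and visit III.
#' @param age_latent_cor magnitude of the negative correlation between age
#'   and the latent trait (0 disables the age effect).
#' @param latent_drift annual per-SD drift of the latent trait between visits:
#'   a participant with baseline latent `z` changes by `latent_drift * z` per
#'   year, so below-average participants decline and above-average ones gain.
#' @param seed integer seed; identical configs give identical cohorts.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 2000L,
                         n_blocks = 30L,
                         block_size = 3L,
                         within_block_corr = 0.9,
                         n_informative_blocks = 10L,
                         effect_size = 0.5,
                         n_noise_features = 200L,
                         near_dup_fraction = 0,
                         test_noise_sd = 1,
                         visit_gap_years = 8,
                         age_latent_cor = 0.2,
                         latent_drift = 0.03,
                         seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size),
    within_block_corr = within_block_corr,
    n_informative_blocks = as.integer(n_informative_blocks),
    effect_size = effect_size,
    n_noise_features = as.integer(n_noise_features),
    near_dup_fraction = near_dup_fraction,
    test_noise_sd = test_noise_sd,
    visit_gap_years = visit_gap_years,
    age_latent_cor = age_latent_cor,
    latent_drift = latent_drift,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid synth_config field '", field, "': ", why, call. = FALSE)
  }
  counts <- c("n_participants", "n_blocks", "block_size",
              "n_informative_blocks", "n_noise_features")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L) fail(f, "must be a nonnegative count")
  }
  if (cfg$n_participants < 4L) fail("n_participants", "must be >= 4")
  if (cfg$n_informative_blocks > cfg$n_blocks) {
    fail("n_informative_blocks", "cannot exceed n_blocks")
  }
  if (cfg$within_block_corr < 0 || cfg$within_block_corr >= 1) {
    fail("within_block_corr", "must lie in [0, 1)")
  }
  if (cfg$effect_size < 0) fail("effect_size", "must be >= 0")
  if (cfg$near_dup_fraction < 0 || cfg$near_dup_fraction > 1) {
    fail("near_dup_fraction", "must lie in [0, 1]")
  }
  if (cfg$test_noise_sd < 0) fail("test_noise_sd", "must be >= 0")
  if (cfg$visit_gap_years <= 0) fail("visit_gap_years", "must be > 0")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

# Expected gap E[z | top quartile] - E[z | bottom quartile] for z ~ N(0,1):
# 2 * dnorm(qnorm(.75)) / .25.
latent_quartile_gap <- function() 2 * stats::dnorm(stats::qnorm(0.75)) / 0.25

# Loading delta on the latent trait that yields a between-extreme-quartile
# standardized mean difference of `e` for a unit-variance feature receiving
# an additional delta * z term: solves delta * gap / sqrt(1 + delta^2) = e.
effect_to_loading <- function(e) {
  if (e == 0) return(0)
  gap <- latent_quartile_gap()
  if (e >= gap) stop("effect_size must be < ", round(gap, 4), call. = FALSE)
  e / sqrt(gap^2 - e^2)
}

#' Generate a synthetic cohort
#'
#' Draws a latent cognition trait per participant, a correlated-block feature
#' table with planted informative blocks, one-hot demographic covariates, and
#' a two-visit cognitive battery (FI, PM, PMM, RT) whose scale, direction and
#' group spread mimic touch-screen batteries: higher FI/PM is better, higher
#' raw RT (milliseconds) and PMM (errors) is worse. The latent trait drifts
#' between visits in proportion to its baseline value, planting improving and
#' declining trajectories.
#'
#' @param config a [synth_config()].
#' @return a list of class `cohort` with elements
#'   \describe{
#'     \item{features}{data.frame, first column `participant_id`, then p
#'       numeric features.}
#'     \item{meta}{data.frame with `feature`, `category`, `visit` per feature.}
#'     \item{battery}{data.frame with raw `FI_I, FI_III, PM_I, PM_III,
#'       PMM_I, PMM_III, RT_I, RT_III, date_I, date_III`.}
#'     \item{truth}{list with `informative_block_ids`, `feature_to_block`
#'       (named character, `NA` for non-block features) and `latent_trait`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  rho <- config$within_block_corr

  pid <- sprintf("P%05d", seq_len(n))

  ## demographics -----------------------------------------------------------
  age <- stats::runif(n, 55, 70)
  sex_male <- stats::rbinom(n, 1, 0.5)
  edu <- sample(c("college", "post_secondary", "secondary", "other"),
                n, replace = TRUE, prob = c(0.55, 0.18, 0.15, 0.12))
  social <- sample(c("under", "lower", "middle", "upper_middle", "upper"),
                   n, replace = TRUE, prob = c(0.15, 0.27, 0.29, 0.22, 0.07))
  smoking <- sample(c("never", "previous", "current"),
                    n, replace = TRUE, prob = c(0.60, 0.36, 0.04))

  ## latent cognition trait -------------------------------------------------
  a <- config$age_latent_cor
  age_std <- as.numeric(scale(age))
  z1 <- sqrt(max(0, 1 - a^2)) * stats::rnorm(n) - a * age_std

  ## block features ---------------------------------------------------------
  delta <- effect_to_loading(config$effect_size)
  n_block_feats <- config$n_blocks * config$block_size
  categories <- c("aseg", "desikan_gw", "desikan_pial", "desikan_white", "desikan_sub")
  feat <- list(); feat_block <- character(0)
  informative <- seq_len(config$n_informative_blocks)
  block_ids <- if (config$n_blocks > 0) sprintf("B%02d", seq_len(config$n_blocks)) else character(0)
  for (b in seq_len(config$n_blocks)) {
    f_b <- stats::rnorm(n)
    for (j in seq_len(config$block_size)) {
      x <- sqrt(rho) * f_b + sqrt(1 - rho) * stats::rnorm(n)
      if (b %in% informative) x <- x + delta * z1
      nm <- sprintf("smri_b%02d_f%d", b, j)
      feat[[nm]] <- x
      feat_block[nm] <- block_ids[b]
    }
  }

  ## noise features (a fraction are near-duplicates of informative features)
  n_noise <- config$n_noise_features
  n_dup <- if (config$n_informative_blocks > 0 && config$block_size > 0) {
    round(config$near_dup_fraction * n_noise)
  } else 0L
  informative_names <- names(feat_block)[feat_block %in% block_ids[informative]]
  for (i in seq_len(n_noise)) {
    nm <- sprintf("noise_%03d", i)
    if (i <= n_dup) {
      src <- feat[[sample(informative_names, 1)]]
      r <- 0.97
      x <- r * as.numeric(scale(src)) + sqrt(1 - r^2) * stats::rnorm(n)
      nm <- sprintf("dup_%03d", i)
    } else {
      x <- stats::rnorm(n)
    }
    feat[[nm]] <- x
    feat_block[nm] <- NA_character_
  }

  ## assemble feature table with one-hot demographics ------------------------
  demo <- data.frame(
    age = age,
    sex_male = sex_male,
    stats::model.matrix(~ 0 + edu)[, , drop = FALSE],
    stats::model.matrix(~ 0 + social)[, , drop = FALSE],
    stats::model.matrix(~ 0 + smoking)[, , drop = FALSE],
    check.names = TRUE
  )
  names(demo) <- sub("^edu", "education_", names(demo))
  names(demo) <- sub("^social", "social_", names(demo))
  names(demo) <- sub("^smoking", "smoking_", names(demo))
  for (nm in names(demo)) feat_block[nm] <- NA_character_

  features <- data.frame(participant_id = pid, demo,
                         as.data.frame(feat), check.names = FALSE)

  smri_names <- names(feat)
  smri_cat <- categories[(seq_along(smri_names) - 1L) %% length(categories) + 1L]
  is_block <- grepl("^smri_b", smri_names)
  smri_cat[is_block] <- categories[
    (as.integer(sub("^smri_b(\\d+)_.*$", "\\1", smri_names[is_block])) - 1L) %%
      length(categories) + 1L]
  meta <- data.frame(
    feature = c(names(demo), smri_names),
    category = c(rep("demographic", ncol(demo)), smri_cat),
    visit = c(rep("I", ncol(demo)), rep("III", length(smri_names))),
    stringsAsFactors = FALSE
  )

  ## visit dates and latent drift -------------------------------------------
  date_I <- as.Date("2008-07-01") + sample.int(1080, n, replace = TRUE) - 540L
  gap_days <- round(config$visit_gap_years * 365.25) +
    sample.int(181, n, replace = TRUE) - 91L
  date_III <- date_I + gap_days
  gap_years <- gap_days / 365.25
  z3 <- z1 + config$latent_drift * z1 * gap_years

  battery <- make_battery(z1, z3, config$test_noise_sd, date_I, date_III, pid)

  truth <- list(
    informative_block_ids = block_ids[informative],
    feature_to_block = feat_block,
    latent_trait = stats::setNames(z1, pid)
  )
  structure(list(features = features, meta = meta, battery = battery,
                 truth = truth, config = config),
            class = "cohort")
}

# Cognitive battery anchored to plausible touch-screen battery scales.
# Slopes/intercepts place the extreme-quartile group means where large
# population batteries put them; higher latent = better cognition, so RT and
# PMM decrease with the latent (higher raw value = worse performance).
make_battery <- function(z1, z3, noise_sd, date_I, date_III, pid) {
  n <- length(z1)
  mk_fi  <- function(z) 6.85 + 1.456 * z + 1.55 * noise_sd * stats::rnorm(n)
  mk_rt  <- function(z, int) exp(int - 0.085 * z + 0.15 * noise_sd * stats::rnorm(n))
  mk_pmm <- function(z) expm1(pmax(0, 1.41 - 0.22 * z + 0.6 * noise_sd * stats::rnorm(n)))
  # latent threshold model: degenerates to a deterministic indicator at zero
  # noise, and to a logistic success-probability model at noise_sd = 1
  mk_pm  <- function(z) as.integer(2.17 + 1.35 * z + noise_sd * stats::rlogis(n) > 0)
  data.frame(
    participant_id = pid,
    FI_I = mk_fi(z1),   FI_III = mk_fi(z3),
    PM_I = mk_pm(z1),   PM_III = mk_pm(z3),
    PMM_I = mk_pmm(z1), PMM_III = mk_pmm(z3),
    RT_I = mk_rt(z1, 6.325), RT_III = mk_rt(z3, 6.41),
    date_I = date_I, date_III = date_III,
    stringsAsFactors = FALSE
  )
}

#' Score a selected feature set against the planted ground truth
#'
#' @param selected character vector of selected feature names.
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @return list with `block_recall` (fraction of informative blocks with at
#'   least one selected member) and `false_positive_count` (selected features
#'   belonging to no informative block).
#' @export
score_selection <- function(selected, truth) {
  selected <- unique(as.character(selected))
  known <- names(truth$feature_to_block)
  bad <- setdiff(selected, known)
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  blocks <- truth$feature_to_block[selected]
  inf <- truth$informative_block_ids
  hit <- inf %in% blocks
  recall <- if (length(inf)) sum(hit) / length(inf) else NA_real_
  fp <- sum(is.na(blocks) | !(blocks %in% inf))
  list(block_recall = recall, false_positive_count = as.integer(fp))
}

#' Write a cohort to disk as plain-text files
#'
#' Emits `features.csv` (participants as rows, first column
#' `participant_id`), `feature_meta.json` (feature -> category/visit),
#' `battery.csv` and `ground_truth.json` under `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$features, file.path(dir, "features.csv"), row.names = FALSE)
  sidecar <- stats::setNames(
    lapply(seq_len(nrow(cohort$meta)), function(i) {
      list(category = cohort$meta$category[i], visit = cohort$meta$visit[i])
    }),
    cohort$meta$feature
  )
  jsonlite::write_json(sidecar, file.path(dir, "feature_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bat <- cohort$battery
  bat$date_I <- as.character(bat$date_I)
  bat$date_III <- as.character(bat$date_III)
  utils::write.csv(bat, file.path(dir, "battery.csv"), row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(informative_block_ids = truth$informative_block_ids,
         feature_to_block = as.list(truth$feature_to_block),
         latent_trait = as.list(truth$latent_trait)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}
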