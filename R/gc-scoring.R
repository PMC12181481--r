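#' @title General Cognition composite scoring and cognitive-class labeling
#' @description Build the PCA-based General Cognition (GC) composite from a
#'   two-visit cognitive battery, assign quartile cognitive classes, and
#'   compute per-participant trajectory slopes.
#' @name gc_scoring
NULL

battery_test_cols <- c("FI_I", "FI_III", "PM_I", "PM_III",
                       "PMM_I", "PMM_III", "RT_I", "RT_III")

#' Transform raw cognitive tests
#'
#' Reaction time has a long right tail and is recorded in milliseconds; pair
#' matching memory is an error count. Both are compressed before the PCA:
#' RT columns are replaced by `log(RT)` and PMM columns by `log(PMM + 1)`.
#' FI and PM are left on their native scales.
#'
#' @param battery data.frame with columns `FI_I, FI_III, PM_I, PM_III, PMM_I,
#'   PMM_III, RT_I, RT_III` (a `participant_id` column and visit dates are
#'   carried through untouched).
#' @return the battery with transformed RT/PMM columns and attribute
#'   `transformed = TRUE`.
#' @export
transform_tests <- function(battery) {
  need <- battery_test_cols
  miss <- setdiff(need, names(battery))
  if (length(miss)) stop("battery lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (isTRUE(attr(battery, "transformed"))) {
    stop("battery already transformed", call. = FALSE)
  }
  id <- battery[["participant_id"]] %||% seq_len(nrow(battery))
  for (col in c("RT_I", "RT_III")) {
    bad <- which(!is.na(battery[[col]]) & battery[[col]] <= 0)
    if (length(bad)) {
      stop("non-positive ", col, " for participant(s): ",
           paste(utils::head(id[bad], 5), collapse = ", "), call. = FALSE)
    }
    battery[[col]] <- log(battery[[col]])
  }
  for (col in c("PMM_I", "PMM_III")) {
    bad <- which(!is.na(battery[[col]]) & battery[[col]] < 0)
    if (length(bad)) {
      stop("negative ", col, " for participant(s): ",
           paste(utils::head(id[bad], 5), collapse = ", "), call. = FALSE)
    }
    battery[[col]] <- log1p(battery[[col]])
  }
  attr(battery, "transformed") <- TRUE
  battery
}

#' Fit the General Cognition composite
#'
#' Standardizes the test columns, extracts the first principal component and
#' sign-normalizes it so that the composite correlates non-negatively with
#' fluid intelligence: larger GC scores then always mean better cognition
#' (equivalently, a higher likelihood of being labeled a Positive-Ager),
#' regardless of the arbitrary sign the eigendecomposition returns.
#'
#' @param battery a transformed battery (see [transform_tests()]), or any
#'   data.frame of numeric test columns.
#' @param cols columns to use; defaults to the eight (4 tests x 2 visits)
#'   battery columns when present, otherwise all numeric columns.
#' @param sign_ref column whose correlation with the composite is forced
#'   non-negative (defaults to `FI_I` when present, else the first column).
#' @param na_action `"drop"` removes participants with any missing test;
#'   `"impute"` replaces missing values by the column mean.
#' @return object of class `gc_result`: `loadings` (unit norm),
#'   `explained_variance_fraction`, `scores` (named per participant),
#'   `kept` (row indices used), plus the centering/scaling used.
#' @export
fit_gc <- function(battery, cols = NULL, sign_ref = NULL,
                   na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  if (is.null(cols)) {
    cols <- if (all(battery_test_cols %in% names(battery))) {
      battery_test_cols
    } else {
      names(battery)[vapply(battery, is.numeric, logical(1))]
    }
  }
  X <- as.matrix(battery[, cols, drop = FALSE])
  if (ncol(X) < 2L) stop("need at least two test columns", call. = FALSE)
  kept <- seq_len(nrow(X))
  if (anyNA(X)) {
    if (na_action == "drop") {
      kept <- which(stats::complete.cases(X))
      X <- X[kept, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(X))) {
        X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
      }
    }
  }
  if (nrow(X) < 8L) stop("need at least 8 complete participants", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance test column(s): ",
         paste(cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  evf <- pc$sdev[1]^2 / sum(pc$sdev^2)

  if (is.null(sign_ref)) sign_ref <- if ("FI_I" %in% cols) "FI_I" else cols[1]
  flip <- gc_sign(scores, X[, sign_ref])
  loadings <- flip * loadings
  scores <- flip * scores

  ids <- battery[["participant_id"]]
  names(scores) <- if (!is.null(ids)) as.character(ids)[kept] else as.character(kept)
  structure(
    list(loadings = loadings, explained_variance_fraction = evf,
         scores = scores, kept = kept, cols = cols,
         center = pc$center, scale = pc$scale, sign_ref = sign_ref),
    class = "gc_result"
  )
}

# +1/-1 factor that makes cor(scores, ref) >= 0; zero correlation keeps +1.
gc_sign <- function(scores, ref) {
  r <- suppressWarnings(stats::cor(scores, ref))
  if (!is.na(r) && r < 0) -1 else 1
}

#' @export
print.gc_result <- function(x, ...) {
  cat("General Cognition composite (first principal component)\n")
  cat(sprintf("  explained variance: %.1f%% of %d tests, n = %d\n",
              100 * x$explained_variance_fraction, length(x$loadings),
              length(x$scores)))
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Assign quartile-based cognitive classes
#'
#' Participants below the first quartile of the GC score are labeled
#' `CognitiveDecliner`, those above the third quartile `PositiveAger`, and
#' the middle half `Maintainer`. Quartiles use the linear-interpolation
#' convention (`quantile` type 7); scores exactly equal to a threshold stay
#' Maintainers, so the extreme groups are defined by strict inequalities.
#'
#' @param scores numeric GC scores (named or not).
#' @return list with `labels` (factor, levels CognitiveDecliner / Maintainer /
#'   PositiveAger), `q1`, `q3`.
#' @export
label_cohort <- function(scores) {
  s <- as.numeric(scores)
  if (length(s) < 4L) stop("need at least 4 participants to form quartiles", call. = FALSE)
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    stop("degenerate score distribution: first and third quartiles coincide", call. = FALSE)
  }
  lab <- rep("Maintainer", length(s))
  lab[s < q[1]] <- "CognitiveDecliner"
  lab[s > q[2]] <- "PositiveAger"
  list(labels = factor(lab, levels = c("CognitiveDecliner", "Maintainer", "PositiveAger")),
       q1 = q[1], q3 = q[2])
}

#' Full GC labeling pipeline
#'
#' Convenience wrapper: transform the raw battery, fit the composite, label
#' quartile groups, and return the binary classification target on the
#' retained (non-Maintainer) participants.
#'
#' @param battery raw (untransformed) cognitive battery.
#' @param ... passed to [fit_gc()].
#' @return list with `gc` (the [fit_gc()] result), `labels`, `q1`, `q3`,
#'   `retained` (participant ids of the two extreme groups) and `y`
#'   (two-level factor over the retained participants, positive class
#'   `PositiveAger`).
#' @export
gc_pipeline <- function(battery, ...) {
  tb <- transform_tests(battery)
  gc <- fit_gc(tb, ...)
  lb <- label_cohort(gc$scores)
  keep <- lb$labels != "Maintainer"
  y <- droplevels(lb$labels[keep])
  y <- as_binary_factor(y, positive = "PositiveAger")
  names(y) <- names(gc$scores)[keep]
  list(gc = gc, labels = lb$labels, q1 = lb$q1, q3 = lb$q3,
       retained = names(gc$scores)[keep], y = y)
}

#' Per-visit GC scores and trajectory slopes
#'
#' The composite is fitted to each visit's four tests separately (each
#' per-visit component sign-normalized against that visit's FI), yielding
#' scores S1 and S3; the trajectory slope is the per-year change
#' `(S3 - S1) / (t3 - t1)` with the visit gap taken from the recorded dates.
#'
#' @param battery transformed battery including `date_I`/`date_III` (Date or
#'   parseable character) or numeric `t_I`/`t_III` times in years.
#' @param labels optional factor of cognitive classes (as from
#'   [label_cohort()]) used for group-mean slopes.
#' @return list with `records` (data.frame `participant_id, S1, S3, t1, t3,
#'   slope`), and `group_means` (named mean slope per label) when labels are
#'   supplied.
#' @export
trajectory_slopes <- function(battery, labels = NULL) {
  if (!isTRUE(attr(battery, "transformed"))) {
    battery <- transform_tests(battery)
  }
  gc1 <- fit_gc(battery, cols = c("FI_I", "PM_I", "PMM_I", "RT_I"), sign_ref = "FI_I")
  gc3 <- fit_gc(battery, cols = c("FI_III", "PM_III", "PMM_III", "RT_III"), sign_ref = "FI_III")
  if (!identical(gc1$kept, gc3$kept)) {
    keep <- intersect(gc1$kept, gc3$kept)
  } else keep <- gc1$kept

  if (all(c("date_I", "date_III") %in% names(battery))) {
    t1 <- as.numeric(as.Date(battery$date_I)) / 365.25
    t3 <- as.numeric(as.Date(battery$date_III)) / 365.25
  } else if (all(c("t_I", "t_III") %in% names(battery))) {
    t1 <- battery$t_I; t3 <- battery$t_III
  } else {
    stop("battery needs date_I/date_III or t_I/t_III", call. = FALSE)
  }
  t1 <- t1[keep]; t3 <- t3[keep]
  if (any(t3 <= t1)) {
    stop("visit III must postdate visit I for all participants", call. = FALSE)
  }
  id <- battery[["participant_id"]]
  id <- if (!is.null(id)) as.character(id)[keep] else as.character(keep)
  rec <- data.frame(
    participant_id = id,
    S1 = unname(gc1$scores[match(keep, gc1$kept)]),
    S3 = unname(gc3$scores[match(keep, gc3$kept)]),
    t1 = t1, t3 = t3, stringsAsFactors = FALSE
  )
  rec$slope <- trajectory_slope(rec$S1, rec$S3, rec$t1, rec$t3)
  out <- list(records = rec)
  if (!is.null(labels)) {
    lab <- labels[keep]
    out$group_means <- tapply(rec$slope, lab, mean)
  }
  out
}

#' Trajectory slope arithmetic
#'
#' @param S1,S3 GC scores at visits I and III.
#' @param t1,t3 visit times in years (`t3 > t1`).
#' @return `(S3 - S1) / (t3 - t1)`, the per-year change in GC score.
#' @export
trajectory_slope <- function(S1, S3, t1, t3) {
  if (any(t3 <= t1)) stop("t3 must exceed t1", call. = FALSE)
  (S3 - S1) / (t3 - t1)
}
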