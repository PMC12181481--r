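#' Stage B configuration
#'
#' @param C_grid ascending positive inverse-regularization values. `C` is the
#'   inverse of the penalty strength: the L1 logistic objective solved at each
#'   grid point is `(1/n) * negative log-likelihood + lambda * ||w||_1` with
#'   `lambda = 1 / (n * C)`, so larger `C` means a weaker penalty. The default
#'   grid is 25 points log-spaced on `[1e-4, 1e4]`.
#' @param epsilon improvement tolerance in AUC units for the smallest-adequate
#'   `C` rule (see [select_c_star()]).
#' @param n_folds stratified cross-validation folds.
#' @param rule `"epsilon"` uses the fixed tolerance; `"one_se"` substitutes
#'   the cross-fold AUC standard deviation at the grid argmax.
#' @return object of class `stage_b_config`.
#' @export
stage_b_config <- function(C_grid = 10^seq(-4, 4, length.out = 25),
                           epsilon = 0.005, n_folds = 5L,
                           rule = c("epsilon", "one_se")) {
  rule <- match.arg(rule)
  if (any(C_grid <= 0)) stop("C_grid values must be positive", call. = FALSE)
  if (is.unsorted(C_grid, strictly = TRUE)) {
    stop("C_grid must be strictly increasing", call. = FALSE)
  }
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  structure(list(C_grid = C_grid, epsilon = epsilon,
                 n_folds = as.integer(n_folds), rule = rule),
            class = "stage_b_config")
}

# glmnet fit over the whole descending-lambda path corresponding to C_grid.
fit_l1_path <- function(X, y, C_grid) {
  std <- standardize_train(X)
  n <- nrow(std$x)
  lambda <- sort(1 / (n * C_grid), decreasing = TRUE)
  fit <- glmnet::glmnet(std$x, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE, thresh = 1e-9)
  list(fit = fit, std = std, lambda = lambda)
}

#' Cross-validated AUC along the L1 regularization path
#'
#' For every `C` in the grid, fits L1-regularized logistic regression
#' (features z-scored with training statistics) and records the mean and
#' standard deviation of the held-out AUC over stratified folds, plus the
#' nonzero-coefficient count of the model refit on the full data at that `C`.
#'
#' @param X data.frame of numeric features.
#' @param y binary labels (both classes in every fold; enforced by
#'   stratification).
#' @param config a [stage_b_config()].
#' @param seed integer seed for the fold assignment.
#' @return data.frame of class `l1_path` with columns `C, lambda, mean_auc,
#'   sd_auc, n_nonzero`, ascending in `C`.
#' @export
l1_auc_path <- function(X, y, config = stage_b_config(), seed = 1L) {
  check_feature_table(X)
  y <- as_binary_factor(y)
  C_grid <- config$C_grid
  folds <- stratified_folds(y, config$n_folds, seed)
  n_C <- length(C_grid)
  auc_mat <- matrix(NA_real_, config$n_folds, n_C)
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    if (nlevels(droplevels(y[!tr])) < 2L || nlevels(droplevels(y[tr])) < 2L) {
      stop("fold ", f, " has a single class; reduce n_folds", call. = FALSE)
    }
    path <- fit_l1_path(X[tr, , drop = FALSE], y[tr], C_grid)
    newx <- standardize_apply(X[!tr, , drop = FALSE], path$std)
    pred <- stats::predict(path$fit, newx = newx, s = path$lambda,
                           type = "response")
    # columns of `pred` follow the descending lambda order = ascending C
    for (j in seq_len(n_C)) auc_mat[f, j] <- auc_score(y[!tr], pred[, j])
  }
  full <- fit_l1_path(X, y, C_grid)
  beta <- as.matrix(full$fit$beta)
  nz <- colSums(abs(beta) > 1e-10)
  out <- data.frame(
    C = C_grid,
    lambda = full$lambda,  # descending lambda pairs with ascending C
    mean_auc = colMeans(auc_mat),
    sd_auc = apply(auc_mat, 2, stats::sd),
    n_nonzero = as.integer(nz)
  )
  class(out) <- c("l1_path", "data.frame")
  attr(out, "n_folds") <- config$n_folds
  attr(out, "seed") <- seed
  out
}

#' Smallest adequate inverse-regularization value
#'
#' Returns the smallest `C*` in the grid for which no improvement above
#' `epsilon` in cross-validated AUC is recorded anywhere in `(C*, C_M]`,
#' i.e. the first grid point whose AUC is within `epsilon` of the best AUC at
#' any larger `C`. The largest grid value trivially qualifies (the interval
#' beyond it is empty), so a choice always exists; with `epsilon = 0` the rule
#' returns the smallest `C` attaining the running maximum from the right.
#'
#' @param path an [l1_auc_path()] result.
#' @param epsilon improvement tolerance in AUC units (`>= 0`).
#' @param rule see [stage_b_config()].
#' @return the selected `C*` (scalar, an element of the grid).
#' @export
select_c_star <- function(path, epsilon = 0.005, rule = c("epsilon", "one_se")) {
  rule <- match.arg(rule)
  if (!nrow(path)) stop("empty regularization path", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  auc <- path$mean_auc
  if (rule == "one_se") epsilon <- path$sd_auc[which.max(auc)]
  m <- length(auc)
  # suffix_max[i] = best AUC strictly beyond grid point i
  suffix_max <- c(rev(cummax(rev(auc)))[-1], -Inf)
  ok <- (suffix_max - auc) <= epsilon
  path$C[which(ok)[1]]
}

#' Stage B: feature subset from the L1 fit at C*
#'
#' Computes the cross-validated AUC path, selects `C*`, refits the
#' L1-regularized logistic model at `C*` on the full training data, and
#' returns the features with nonzero coefficients.
#'
#' @param X data.frame of numeric features (typically the Stage A output).
#' @param y binary labels.
#' @param config a [stage_b_config()].
#' @param seed integer seed (fold assignment).
#' @return list with `selected` (character), `C_star`, `path` (the
#'   [l1_auc_path()]), `coefficients` (named, nonzero entries at `C*`) and
#'   `trace` (`l1_zero_coef` events for the dropped features).
#' @export
stage_b <- function(X, y, config = stage_b_config(), seed = 1L) {
  if (!ncol(X)) stop("empty feature table", call. = FALSE)
  y <- as_binary_factor(y)
  path <- l1_auc_path(X, y, config, seed)
  C_star <- select_c_star(path, epsilon = config$epsilon, rule = config$rule)
  full <- fit_l1_path(X, y, config$C_grid)
  lam_star <- 1 / (nrow(X) * C_star)
  j <- which.min(abs(full$lambda - lam_star))
  beta <- as.matrix(full$fit$beta)[, j]
  selected <- names(beta)[abs(beta) > 1e-10]
  if (!length(selected)) {
    stop("all coefficients are zero at C* = ", signif(C_star, 4),
         "; consider a larger epsilon or extending the C grid", call. = FALSE)
  }
  dropped <- setdiff(names(X), selected)
  trace <- if (length(dropped)) {
    trace_event(dropped, "stage_b", "l1_zero_coef", 0)
  } else new_trace()
  list(selected = selected, C_star = C_star, path = path,
       coefficients = beta[selected], trace = trace)
}

#' @export
print.l1_path <- function(x, ...) {
  cat("L1 logistic regularization path (", nrow(x), " values of C)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
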