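#' Search-space dimensions for the Bayesian tuner
#'
#' @param lower,upper inclusive bounds.
#' @param log if `TRUE`, the dimension is searched on a log10 scale.
#' @param values admissible values of a categorical dimension.
#' @return a dimension descriptor used by [search_space()].
#' @name dimensions
NULL

#' @rdname dimensions
#' @export
dim_integer <- function(lower, upper) {
  stopifnot(lower <= upper)
  list(type = "integer", lower = as.integer(lower), upper = as.integer(upper))
}

#' @rdname dimensions
#' @export
dim_numeric <- function(lower, upper, log = FALSE) {
  stopifnot(lower < upper, !log || lower > 0)
  list(type = "numeric", lower = lower, upper = upper, log = log)
}

#' @rdname dimensions
#' @export
dim_categorical <- function(values) {
  stopifnot(length(values) >= 1)
  list(type = "categorical", values = values)
}

#' Define a search space
#'
#' @param ... named dimensions created with [dim_integer()], [dim_numeric()]
#'   or [dim_categorical()].
#' @param budget total number of objective evaluations.
#' @param n_init random/space-filling evaluations before the surrogate model
#'   takes over proposals.
#' @param seed integer seed for the whole optimization.
#' @return object of class `search_space`.
#' @export
search_space <- function(..., budget = 50L, n_init = 10L, seed = 1L) {
  dims <- list(...)
  if (!length(dims) || is.null(names(dims)) || any(names(dims) == "")) {
    stop("all dimensions must be named", call. = FALSE)
  }
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)
  structure(list(dims = dims, budget = as.integer(budget),
                 n_init = as.integer(min(n_init, budget)),
                 seed = as.integer(seed)),
            class = "search_space")
}

space_size <- function(space) {
  prod(vapply(space$dims, function(d) {
    switch(d$type,
           integer = d$upper - d$lower + 1,
           categorical = length(d$values),
           numeric = Inf)
  }, numeric(1)))
}

# Enumerate all configs of a finite space (list of named lists).
space_enumerate <- function(space) {
  grids <- lapply(space$dims, function(d) {
    switch(d$type,
           integer = seq(d$lower, d$upper),
           categorical = d$values)
  })
  g <- expand.grid(grids, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

space_sample <- function(space, n) {
  lapply(seq_len(n), function(i) {
    cfg <- lapply(space$dims, function(d) {
      switch(d$type,
             integer = sample(seq(d$lower, d$upper), 1),
             categorical = d$values[[sample.int(length(d$values), 1)]],
             numeric = {
               u <- stats::runif(1)
               if (isTRUE(d$log)) {
                 10^(log10(d$lower) + u * (log10(d$upper) - log10(d$lower)))
               } else d$lower + u * (d$upper - d$lower)
             })
    })
    stats::setNames(cfg, names(space$dims))
  })
}

# Encode a config on [0, 1]^d for the GP kernel.
space_encode <- function(space, cfg) {
  unlist(lapply(names(space$dims), function(nm) {
    d <- space$dims[[nm]]
    v <- cfg[[nm]]
    switch(d$type,
           integer = if (d$upper > d$lower) (v - d$lower) / (d$upper - d$lower) else 0.5,
           categorical = {
             i <- match(v, d$values)
             if (length(d$values) > 1) (i - 1) / (length(d$values) - 1) else 0.5
           },
           numeric = if (isTRUE(d$log)) {
             (log10(v) - log10(d$lower)) / (log10(d$upper) - log10(d$lower))
           } else (v - d$lower) / (d$upper - d$lower))
  }))
}

cfg_key <- function(cfg) paste(vapply(cfg, function(v) format(v, digits = 12), ""),
                               collapse = "|")

# Zero-mean GP with squared-exponential kernel; length-scale and nugget picked
# by log marginal likelihood over a small grid (sample sizes here are tiny).
gp_fit <- function(X, y) {
  n <- nrow(X)
  ymu <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ymu) / ysd
  D2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in c(0.1, 0.2, 0.5, 1) * sqrt(max(1, ncol(X)))) {
    K0 <- exp(-D2 / (2 * ell^2))
    for (s2 in c(1e-6, 1e-4, 1e-2)) {
      K <- K0 + diag(s2, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
      if (is.null(best) || ll > best$ll) {
        best <- list(ll = ll, ell = ell, s2 = s2, ch = ch, alpha = alpha)
      }
    }
  }
  c(best, list(X = X, ymu = ymu, ysd = ysd))
}

gp_predict <- function(gp, Xnew) {
  cross <- -2 * Xnew %*% t(gp$X)
  d2 <- sweep(sweep(cross, 2, rowSums(gp$X^2), "+"), 1, rowSums(Xnew^2), "+")
  d2[d2 < 0] <- 0
  Ks <- exp(-d2 / (2 * gp$ell^2))
  mu <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$ch), t(Ks))
  var <- pmax(1e-12, 1 + gp$s2 - colSums(v^2))
  list(mean = mu * gp$ysd + gp$ymu, sd = sqrt(var) * gp$ysd)
}

expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian optimization of a black-box objective
#'
#' Sequential model-based maximization: after `n_init` seeded random
#' evaluations, a Gaussian-process surrogate (squared-exponential kernel on
#' the unit-cube-encoded space) proposes the candidate maximizing expected
#' improvement. Finite spaces (all dimensions integer/categorical, at most
#' 5000 combinations) are enumerated, and already-evaluated configurations
#' are never re-proposed, so a budget covering the space visits all of it;
#' continuous spaces draw 500 fresh candidates per iteration. Objective
#' errors are caught and logged as failed trials.
#'
#' @param objective function taking a named config list, returning a scalar
#'   to maximize (e.g. cross-validated AUC).
#' @param space a [search_space()].
#' @return list with `best_config`, `best_value`, and `trials` (data.frame
#'   with one row per evaluation: the config, `value`, and `error` flag).
#' @export
bayes_opt_tune <- function(objective, space) {
  stopifnot(inherits(space, "search_space"))
  set.seed(fan_seed(space$seed, "bayes_opt"))
  finite <- is.finite(space_size(space)) && space_size(space) <= 5000
  all_cfg <- if (finite) space_enumerate(space) else NULL

  evaluated <- character(0)
  trials <- list()
  values <- numeric(0)
  configs <- list()

  eval_cfg <- function(cfg) {
    val <- tryCatch(objective(cfg), error = function(e) {
      structure(NA_real_, msg = conditionMessage(e))
    })
    err <- is.na(val)
    configs[[length(configs) + 1L]] <<- cfg
    values <<- c(values, as.numeric(val))
    evaluated <<- c(evaluated, cfg_key(cfg))
    trials[[length(trials) + 1L]] <<- c(cfg, list(
      value = as.numeric(val), error = err,
      message = if (err) attr(val, "msg") else NA_character_
    ))
  }

  propose_random <- function() {
    if (finite) {
      pool <- all_cfg[!vapply(all_cfg, cfg_key, "") %in% evaluated]
      if (!length(pool)) return(NULL)
      pool[[sample.int(length(pool), 1)]]
    } else {
      for (i in 1:50) {
        cfg <- space_sample(space, 1)[[1]]
        if (!cfg_key(cfg) %in% evaluated) return(cfg)
      }
      space_sample(space, 1)[[1]]
    }
  }

  # initial design
  n_init <- space$n_init
  for (i in seq_len(n_init)) {
    cfg <- propose_random()
    if (is.null(cfg)) break
    eval_cfg(cfg)
  }

  while (length(values) < space$budget) {
    cand <- if (finite) {
      all_cfg[!vapply(all_cfg, cfg_key, "") %in% evaluated]
    } else {
      space_sample(space, 500L)
    }
    if (!length(cand)) break
    ok <- which(!is.na(values))
    cfg <- if (length(ok) >= 2L && stats::sd(values[ok]) > 0) {
      Xobs <- do.call(rbind, lapply(configs[ok], function(cc) space_encode(space, cc)))
      gp <- gp_fit(Xobs, values[ok])
      Xc <- do.call(rbind, lapply(cand, function(cc) space_encode(space, cc)))
      pr <- gp_predict(gp, Xc)
      ei <- expected_improvement(pr$mean, pr$sd, max(values[ok]))
      cand[[which.max(ei)]]
    } else {
      propose_random()
    }
    if (is.null(cfg)) break
    eval_cfg(cfg)
  }

  if (all(is.na(values))) {
    stop("objective failed on every trial; first error: ",
         trials[[1]]$message, call. = FALSE)
  }
  best <- which.max(values)
  tr <- do.call(rbind, lapply(trials, function(t) {
    as.data.frame(lapply(t, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  list(best_config = configs[[best]], best_value = values[best], trials = tr)
}
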