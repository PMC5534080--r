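#' Covariate specification for the simulation engine
#'
#' Describes one covariate of a simulation design. Binary covariates are
#' Bernoulli(p) indicators with a single log-hazard-ratio coefficient;
#' polytomous covariates are sampled with replacement from a list of labelled
#' levels with given weights and carry one coefficient per level.
#'
#' @param name Column name.
#' @param kind `"binary"` or `"polytomous"`.
#' @param bernoulli_p Success probability in (0, 1) (binary only).
#' @param levels Character vector of at least 3 level labels (polytomous only).
#' @param weights Sampling weights, one per level, summing to 1. Default equal.
#' @param coefficient Log hazard ratio: a scalar for binary covariates, a
#'   vector with one value per level for polytomous covariates.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, kind = c("binary", "polytomous"),
                           bernoulli_p = NULL, levels = NULL, weights = NULL,
                           coefficient) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (is.null(bernoulli_p) || length(bernoulli_p) != 1L ||
        bernoulli_p <= 0 || bernoulli_p >= 1)
      stop("binary covariate '", name, "': bernoulli_p must lie strictly in (0,1)")
    if (length(coefficient) != 1L)
      stop("binary covariate '", name, "': coefficient must be a scalar")
    levels <- NULL; weights <- NULL
  } else {
    if (is.null(levels) || length(levels) < 3L)
      stop("polytomous covariate '", name, "': needs at least 3 levels")
    if (anyDuplicated(levels)) stop("duplicate levels in covariate '", name, "'")
    if (is.null(weights)) weights <- rep(1 / length(levels), length(levels))
    if (length(weights) != length(levels) || any(weights <= 0) ||
        abs(sum(weights) - 1) > 1e-8)
      stop("polytomous covariate '", name,
           "': weights must be positive and sum to 1")
    if (length(coefficient) != length(levels))
      stop("polytomous covariate '", name, "': one coefficient per level required")
    bernoulli_p <- NULL
  }
  structure(list(name = name, kind = kind, bernoulli_p = bernoulli_p,
                 levels = levels, weights = weights,
                 coefficient = coefficient),
            class = "covariate_spec")
}

#' Simulation design for Weibull proportional-hazards time-to-event data
#'
#' One executable simulation scenario: covariate distribution, Weibull event
#' time model, Weibull censoring model and target censoring rate. Event times
#' follow a proportional-hazards Weibull model with baseline hazard
#' h0(t) = (shape/rho^shape) t^(shape-1): the per-subject Weibull scale is
#' lambda = exp(-intercept/shape - sum(beta_j x_j)/shape), so the cumulative
#' hazard is t^shape * exp(intercept + sum(beta_j x_j)) and each coefficient
#' acts as a log hazard ratio.
#'
#' @param design_id Label for the design.
#' @param n Sample size of one generated dataset.
#' @param covariates List of [covariate_spec()] objects.
#' @param interactions Optional list of interactions, each a list with fields
#'   `a`, `b` (covariate names) and `coefficient`. A binary covariate enters
#'   the product as its 0/1 value; a polytomous covariate as an equally spaced
#'   level score on \[-1, 1\].
#' @param event_shape Weibull shape of the event times (> 0); > 1 gives an
#'   increasing hazard, < 1 decreasing, = 1 constant (exponential).
#' @param intercept Intercept beta_0 = log(rho^-shape) of the linear predictor.
#' @param censor_shape Weibull shape of the censoring distribution.
#' @param censor_scale Weibull scale of the censoring distribution, or `NA`
#'   to calibrate numerically against `target_censoring` (see
#'   [calibrate_censoring()]).
#' @param target_censoring Desired censoring fraction in \[0, 1).
#' @param hazard_trend `"increasing"`, `"decreasing"` or `"constant"`; must
#'   agree with `event_shape`.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(design_id, n, covariates, interactions = list(),
                       event_shape, intercept, censor_shape,
                       censor_scale = NA_real_, target_censoring,
                       hazard_trend = c("increasing", "decreasing", "constant")) {
  hazard_trend <- match.arg(hazard_trend)
  if (length(covariates) == 0L) stop("design needs at least one covariate")
  if (!all(vapply(covariates, inherits, TRUE, "covariate_spec")))
    stop("covariates must be a list of covariate_spec objects")
  if (event_shape <= 0) stop("event_shape must be positive")
  if (censor_shape <= 0) stop("censor_shape must be positive")
  if (target_censoring < 0 || target_censoring >= 1)
    stop("target_censoring must lie in [0, 1)")
  implied <- if (event_shape > 1) "increasing" else
    if (event_shape < 1) "decreasing" else "constant"
  if (implied != hazard_trend)
    stop("hazard_trend '", hazard_trend, "' inconsistent with event_shape ",
         event_shape)
  nm <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate covariate names")
  for (ia in interactions) {
    if (!all(c("a", "b", "coefficient") %in% names(ia)))
      stop("each interaction needs fields a, b, coefficient")
    if (!all(c(ia$a, ia$b) %in% nm))
      stop("interaction references unknown covariate(s): ", ia$a, ", ", ia$b)
  }
  structure(list(design_id = design_id, n = as.integer(n),
                 covariates = covariates, interactions = interactions,
                 event_shape = event_shape, intercept = intercept,
                 censor_shape = censor_shape, censor_scale = censor_scale,
                 target_censoring = target_censoring,
                 hazard_trend = hazard_trend),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("Simulation design '%s': n=%d, %d covariates, %s hazard, %.0f%% censoring target\n",
              x$design_id, x$n, length(x$covariates), x$hazard_trend,
              100 * x$target_censoring))
  invisible(x)
}

#' Sample a covariate matrix from a list of covariate specifications
#'
#' Binary covariates are drawn Bernoulli(p); polytomous covariates by sampling
#' with replacement from their level list with the specified weights.
#'
#' @param spec_list List of [covariate_spec()] objects (non-empty).
#' @param n Number of subjects (>= 1).
#' @return A data.frame with `n` rows; binary columns are 0/1 numeric,
#'   polytomous columns factors with the full level set.
#' @export
sample_covariates <- function(spec_list, n) {
  if (length(spec_list) == 0L) stop("spec_list must not be empty")
  if (n < 1L) stop("n must be at least 1")
  cols <- lapply(spec_list, function(sp) {
    if (sp$kind == "binary") {
      stats::rbinom(n, 1L, sp$bernoulli_p)
    } else {
      factor(sample(sp$levels, n, replace = TRUE, prob = sp$weights),
             levels = sp$levels)
    }
  })
  names(cols) <- vapply(spec_list, `[[`, "", "name")
  as.data.frame(cols, optional = TRUE)
}

# Numeric value a covariate contributes to a product interaction term:
# binary -> its 0/1 value, polytomous -> equally spaced level score on [-1,1].
interaction_value <- function(sp, column) {
  if (sp$kind == "binary") as.numeric(column)
  else seq(-1, 1, length.out = length(sp$levels))[as.integer(column)]
}

#' Per-subject Weibull scale of the proportional-hazards event model
#'
#' Evaluates lambda_i = exp(-beta_0/shape - sum_j beta_j x_ij / shape), the
#' Weibull scale parameter of subject i's event-time distribution. Polytomous
#' covariates contribute the coefficient of their observed level; interaction
#' terms contribute coefficient * v(a) * v(b) with the numeric encodings
#' described in [sim_design()].
#'
#' @param design A [sim_design()].
#' @param X Covariate data.frame with columns matching the design.
#' @return Positive numeric vector of per-subject Weibull scales.
#' @export
linear_predictor_scale <- function(design, X) {
  nm <- vapply(design$covariates, `[[`, "", "name")
  if (!all(nm %in% names(X)))
    stop("covariate columns missing from X: ",
         paste(setdiff(nm, names(X)), collapse = ", "))
  lp <- rep(design$intercept, nrow(X))
  for (sp in design$covariates) {
    col <- X[[sp$name]]
    if (sp$kind == "binary") {
      if (!all(col %in% c(0, 1))) stop("binary covariate '", sp$name,
                                       "' has values outside {0,1}")
      lp <- lp + sp$coefficient * as.numeric(col)
    } else {
      idx <- if (is.factor(col)) match(as.character(col), sp$levels)
             else match(col, sp$levels)
      if (anyNA(idx)) stop("covariate '", sp$name, "' has values outside its level set")
      lp <- lp + sp$coefficient[idx]
    }
  }
  specs <- stats::setNames(design$covariates, nm)
  for (ia in design$interactions) {
    va <- interaction_value(specs[[ia$a]], X[[ia$a]])
    vb <- interaction_value(specs[[ia$b]], X[[ia$b]])
    lp <- lp + ia$coefficient * va * vb
  }
  exp(-lp / design$event_shape)
}

#' Generate Weibull proportional-hazards event times
#'
#' Inverts the cumulative hazard: T = lambda * (-log U)^(1/shape), so the
#' event time of subject i is Weibull with the design's shape and subject
#' scale lambda_i; with shape 1 and constant lambda this is exponential with
#' mean lambda.
#'
#' @param design A [sim_design()] (supplies the shape).
#' @param lambda Per-subject scales from [linear_predictor_scale()].
#' @param u Optional uniform draws (for reproducible inversion); defaults to
#'   `runif(length(lambda))`.
#' @return Strictly positive event times.
#' @export
gen_event_times <- function(design, lambda, u = NULL) {
  if (design$event_shape <= 0) stop("event shape must be positive")
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (is.null(u)) u <- stats::runif(length(lambda))
  lambda * (-log(u))^(1 / design$event_shape)
}

# Weibull censoring times for a given scale, by the same inversion.
gen_censor_times <- function(design, scale, u) {
  scale * (-log(u))^(1 / design$censor_shape)
}

#' Calibrate the censoring scale to a target censoring rate
#'
#' Monte-Carlo root finding: with a dedicated probe seed, draws `n_probe`
#' subjects' latent event times and censoring uniforms once, then bisects on
#' log(censoring scale) until the empirical censoring fraction
#' `mean(T > C(scale))` matches the design's target. Using common random
#' numbers makes the censoring fraction monotone in the scale, so bisection
#' converges deterministically.
#'
#' @param design A [sim_design()] with `target_censoring` set.
#' @param n_probe Probe sample size (default 10000).
#' @param tolerance Acceptable absolute deviation of the achieved censoring
#'   fraction (default 0.02).
#' @param probe_seed Seed for the probe sample (fixed by default so the
#'   calibrated scale is a deterministic property of the design).
#' @return The calibrated censoring scale (a positive number; `Inf` when the
#'   target is 0, i.e. no censoring).
#' @export
calibrate_censoring <- function(design, n_probe = 10000L, tolerance = 0.02,
                                probe_seed = 8675309L) {
  target <- design$target_censoring
  if (target == 0) return(Inf)
  probe <- withr_seed(probe_seed, {
    X <- sample_covariates(design$covariates, n_probe)
    lam <- linear_predictor_scale(design, X)
    list(tev = gen_event_times(design, lam), uc = stats::runif(n_probe))
  })
  rate <- function(log_scale) {
    cen <- gen_censor_times(design, exp(log_scale), probe$uc)
    mean(probe$tev > cen)
  }
  lo <- -20; hi <- 20
  # censoring fraction decreases as the censoring scale grows
  for (k in 1:20) {
    if (rate(lo) >= target) break
    lo <- lo - 10
  }
  for (k in 1:20) {
    if (rate(hi) <= target) break
    hi <- hi + 10
  }
  if (rate(lo) < target || rate(hi) > target)
    stop(sprintf("censoring calibration failed: achievable range [%.3f, %.3f] misses target %.3f",
                 rate(hi), rate(lo), target))
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    r <- rate(mid)
    if (abs(r - target) <= tolerance / 2) return(exp(mid))
    if (r > target) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Session cache of calibrated censoring scales, keyed by design content.
.calib_cache <- new.env(parent = emptyenv())

design_cache_key <- function(design) {
  paste(utils::capture.output(utils::str(design[setdiff(names(design), "n")])),
        collapse = "\n")
}

#' Resolve a design's censoring scale
#'
#' Returns the design with `censor_scale` filled in, calibrating it (and
#' caching the result for the session) when it is `NA`.
#'
#' @param design A [sim_design()].
#' @inheritParams calibrate_censoring
#' @return The design with a concrete `censor_scale`.
#' @export
resolve_design <- function(design, n_probe = 10000L, tolerance = 0.02,
                           probe_seed = 8675309L) {
  if (!is.na(design$censor_scale)) return(design)
  key <- design_cache_key(design)
  if (is.null(.calib_cache[[key]]))
    .calib_cache[[key]] <- calibrate_censoring(design, n_probe, tolerance,
                                               probe_seed)
  design$censor_scale <- .calib_cache[[key]]
  design
}

#' Generate one dataset from a simulation design
#'
#' Samples covariates, latent Weibull event and censoring times, and returns
#' the observed right-censored dataset with `time = min(T, C)` and
#' `event = I(T <= C)`. Reproducible: the same seed yields a bit-identical
#' dataset.
#'
#' @param design A [sim_design()]; an `NA` censoring scale is calibrated
#'   automatically via [resolve_design()].
#' @param seed Integer seed.
#' @param n Optional override of the design's sample size.
#' @return A `surv_data` object with latent times retained.
#' @export
gen_dataset <- function(design, seed, n = design$n) {
  design <- resolve_design(design)
  withr_seed(seed, {
    X <- sample_covariates(design$covariates, n)
    lam <- linear_predictor_scale(design, X)
    tev <- gen_event_times(design, lam)
    cen <- if (is.infinite(design$censor_scale)) rep(Inf, n)
           else gen_censor_times(design, design$censor_scale, stats::runif(n))
    survival_dataset(pmin(tev, cen), as.integer(tev <= cen), X,
                     latent_event = tev, latent_censor = cen,
                     design_id = design$design_id)
  })
}

# -- the built-in design registry -------------------------------------------

binary_family_params <- function(trend) {
  switch(trend,
    decreasing = list(shape = 0.8, b0 = -0.98, cshape = 0.4,
                      beta = c(0.5, -0.045, 0.6, -0.03, -2, 0.5, 0.25, -0.04, 0.33, 0.3)),
    increasing = list(shape = 1.5, b0 = -1.44, cshape = 2.4,
                      beta = c(0.1, -0.8, 0.5, -0.2, -3, 0.7, 0.2, 0.4, 0.3, 0)),
    constant   = list(shape = 1.0, b0 = 0.9, cshape = 1.0,
                      beta = c(0.4, -0.7, 1, -2, -3, 0.7, 0.06, 0.5, -0.43, 0.3)))
}

poly_event_params <- function(trend) {
  switch(trend,
    decreasing = list(shape = 0.5, cshape = 0.4),
    increasing = list(shape = 1.5, cshape = 1.2),
    constant   = list(shape = 1.0, cshape = 1.1))
}

binary_specs <- function(beta, prefix = "x", p = 0.5) {
  lapply(seq_along(beta), function(j)
    covariate_spec(paste0(prefix, j), "binary", bernoulli_p = p,
                   coefficient = beta[j]))
}

poly_specs <- function(k, prefix = "z", nlev = c(3L, 4L, 5L)) {
  lapply(seq_len(k), function(j) {
    L <- nlev[((j - 1L) %% length(nlev)) + 1L]
    covariate_spec(paste0(prefix, j), "polytomous",
                   levels = paste0("c", seq_len(L)),
                   coefficient = seq(-1, 1, length.out = L))
  })
}

mixed_specs <- function() {
  c(binary_specs(c(0.5, -0.8, 1, -0.5, 0.7), prefix = "x"),
    poly_specs(5L, prefix = "z"))
}

#' The built-in registry of 22 simulation designs
#'
#' Four covariate families: six binary designs (ten Bernoulli(0.5) covariates
#' with the three printed coefficient vectors/intercepts by hazard trend), six
#' polytomous designs (ten covariates with 3/4/5 cyclic level counts, equal
#' weights, level coefficients equally spaced on \[-1, 1\]), six mixed designs
#' (five binary + five polytomous covariates) and four interaction designs
#' (mixed covariates plus two binary-by-polytomous product terms with
#' coefficients +0.7 and -0.7). Censoring scales are left `NA` and calibrated
#' on demand to the per-design target rates.
#'
#' @return Named list of 22 [sim_design()] objects.
#' @export
builtin_designs <- function() {
  designs <- list()
  add <- function(d) designs[[d$design_id]] <<- d

  btab <- data.frame(n = c(100L, 100L, 250L, 1000L, 1500L, 2000L),
                     cens = c(0.8, 0.5, 0.2, 0.8, 0.5, 0.2),
                     trend = c("increasing", "decreasing", "constant",
                               "increasing", "decreasing", "constant"))
  for (i in seq_len(6)) {
    pp <- binary_family_params(btab$trend[i])
    add(sim_design(paste0("binary", i), btab$n[i],
                   binary_specs(pp$beta), event_shape = pp$shape,
                   intercept = pp$b0, censor_shape = pp$cshape,
                   target_censoring = btab$cens[i], hazard_trend = btab$trend[i]))
  }

  ptab <- data.frame(n = c(100L, 100L, 250L, 1000L, 1500L, 2000L),
                     cens = c(0.2, 0.8, 0.5, 0.2, 0.8, 0.5),
                     trend = c("increasing", "constant", "decreasing",
                               "increasing", "constant", "decreasing"))
  for (i in seq_len(6)) {
    pp <- poly_event_params(ptab$trend[i])
    add(sim_design(paste0("poly", i), ptab$n[i], poly_specs(10L),
                   event_shape = pp$shape, intercept = 0,
                   censor_shape = pp$cshape,
                   target_censoring = ptab$cens[i], hazard_trend = ptab$trend[i]))
  }

  mtab <- data.frame(n = c(1000L, 100L, 250L, 1000L, 1500L, 2000L),
                     cens = c(0.2, 0.8, 0.5, 0.2, 0.8, 0.5),
                     trend = c("increasing", "decreasing", "constant",
                               "increasing", "decreasing", "constant"))
  for (i in seq_len(6)) {
    pp <- poly_event_params(mtab$trend[i])
    add(sim_design(paste0("mixed", i), mtab$n[i], mixed_specs(),
                   event_shape = pp$shape, intercept = 0,
                   censor_shape = pp$cshape,
                   target_censoring = mtab$cens[i], hazard_trend = mtab$trend[i]))
  }

  itab <- data.frame(n = c(100L, 100L, 1000L, 1500L),
                     cens = c(0.2, 0.5, 0.2, 0.5),
                     trend = c("increasing", "decreasing", "increasing",
                               "decreasing"))
  for (i in seq_len(4)) {
    pp <- poly_event_params(itab$trend[i])
    add(sim_design(paste0("interact", i), itab$n[i], mixed_specs(),
                   interactions = list(
                     list(a = "x1", b = "z1", coefficient = 0.7),
                     list(a = "x2", b = "z2", coefficient = -0.7)),
                   event_shape = pp$shape, intercept = 0,
                   censor_shape = pp$cshape,
                   target_censoring = itab$cens[i], hazard_trend = itab$trend[i]))
  }
  designs
}

#' Look up one built-in design by id
#' @param design_id One of the ids in [builtin_designs()], e.g. `"binary2"`.
#' @return A [sim_design()].
#' @export
get_design <- function(design_id) {
  reg <- builtin_designs()
  if (!design_id %in% names(reg))
    stop("unknown design id '", design_id, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[design_id]]
}

#' Export a simulation design as a structured config file
#'
#' Writes every field of the design (covariates, interactions, event and
#' censoring parameters) as YAML, so a design can be archived alongside the
#' datasets it generated and reloaded with [read_design()].
#'
#' @param design A [sim_design()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  x <- unclass(design)
  x$covariates <- lapply(x$covariates, unclass)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Load a simulation design from a config file written by [write_design()]
#' @param path YAML path.
#' @return A validated [sim_design()].
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  covs <- lapply(x$covariates, function(cv)
    covariate_spec(cv$name, cv$kind, bernoulli_p = cv$bernoulli_p,
                   levels = unlist(cv$levels), weights = unlist(cv$weights),
                   coefficient = unlist(cv$coefficient)))
  sim_design(x$design_id, x$n, covs, interactions = x$interactions,
             event_shape = x$event_shape, intercept = x$intercept,
             censor_shape = x$censor_shape,
             censor_scale = if (is.null(x$censor_scale)) NA_real_ else x$censor_scale,
             target_censoring = x$target_censoring,
             hazard_trend = x$hazard_trend)
}
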