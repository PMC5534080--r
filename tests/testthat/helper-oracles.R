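# Shared fixtures and independent brute-force oracles for the test suite.

# Random small right-censored dataset with mixed covariate types.
rand_surv_data <- function(n, censor_frac = 0.3, levels5 = TRUE) {
  tm <- round(rexp(n), 3)
  ev <- as.integer(runif(n) > censor_frac)
  if (sum(ev) == 0) ev[sample.int(n, 1)] <- 1L
  cov <- data.frame(
    xb = rbinom(n, 1, 0.5),
    xf = factor(sample(letters[1:4], n, replace = TRUE)),
    xm = if (levels5) factor(sample(LETTERS[1:5], n, replace = TRUE))
         else rnorm(n))
  survival_dataset(tm, ev, cov)
}

# Exhaustive search over every admissible split of every covariate, using the
# R reference statistics; independent of the C++ search path.
brute_force_best_split <- function(data, rule, min_node_size = 1L,
                                   min_events = 1L) {
  n <- n_subjects(data)
  sc <- logrank_scores(data$time, data$event)$scores
  s2 <- stats::var(sc)
  stat_of <- function(left) {
    r1 <- sum(left)
    if (r1 < min_node_size || n - r1 < min_node_size) return(NA_real_)
    if (sum(data$event[left]) < min_events ||
        sum(data$event[!left]) < min_events) return(NA_real_)
    if (rule == "logrank") {
      tryCatch(abs(logrank_statistic(data$time, data$event, left)),
               error = function(e) NA_real_)
    } else {
      if (s2 <= 0) return(NA_real_)
      abs(sum(sc[left]) - r1 * mean(sc)) / sqrt(r1 * (1 - r1 / n) * s2)
    }
  }
  best <- list(stat = -Inf, left = NULL)
  for (v in names(data$covariates)) {
    x <- data$covariates[[v]]
    lefts <- if (is.factor(x)) {
      lv <- levels(droplevels(x))
      L <- length(lv)
      if (L < 2) list()
      else lapply(seq_len(2^(L - 1) - 1), function(mask) {
        sub <- lv[bitwAnd(mask, bitwShiftL(1L, seq_len(L) - 1L)) > 0L]
        droplevels(x) %in% sub
      })
    } else {
      u <- sort(unique(x))
      if (length(u) < 2) list()
      else lapply((u[-length(u)] + u[-1]) / 2, function(c) x <= c)
    }
    for (left in lefts) {
      s <- stat_of(left)
      if (!is.na(s) && s > best$stat + 1e-12) best <- list(stat = s, left = left)
    }
  }
  if (!is.finite(best$stat)) return(NULL)
  best
}

# Reconstruct the left-child indicator implied by a best_split() result.
split_left_indicator <- function(data, bs) {
  x <- data$covariates[[bs$variable]]
  if (!is.null(bs$threshold)) x <= bs$threshold
  else as.character(x) %in% bs$levels_left
}

# A tiny design used across tests: single strong binary covariate.
strong_binary_design <- function(n = 250L, beta = -3) {
  sim_design("strong_binary", n,
             covariates = list(
               covariate_spec("x1", "binary", bernoulli_p = 0.5,
                              coefficient = beta),
               covariate_spec("x2", "binary", bernoulli_p = 0.5,
                              coefficient = 0)),
             event_shape = 1, intercept = 0, censor_shape = 1,
             target_censoring = 0.2, hazard_trend = "constant")
}
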