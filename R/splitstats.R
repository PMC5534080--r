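#' Log-rank scores for right-censored observations
#'
#' Transforms censored survival data into per-subject rank scores
#' a_l = delta_l - sum_{k=1}^{gamma_l} delta_k / (N - gamma_k + 1), computed
#' over the time ordering with events placed before censorings at tied times
#' (gamma is the rank in that ordering). For fully uncensored data with
#' distinct times the scores sum to zero.
#'
#' @param time Observed times (non-negative).
#' @param event Event indicators (1 = event).
#' @return An object of class `logrank_scores`: list with `scores` (in input
#'   order), `ranks` (position of each subject in the tie-resolved time
#'   ordering), `at_risk` (N - rank + 1), `mean` and `variance` (sample
#'   variance, divisor N - 1).
#' @export
logrank_scores <- function(time, event) {
  n <- length(time)
  if (n < 1L) stop("empty input")
  if (any(time < 0)) stop("times must be non-negative")
  ord <- order(time, -event)
  cum <- cumsum(event[ord] / (n - seq_len(n) + 1))
  a_sorted <- event[ord] - cum
  scores <- numeric(n)
  scores[ord] <- a_sorted
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  structure(list(scores = scores, ranks = ranks, at_risk = n - ranks + 1L,
                 mean = mean(scores),
                 variance = if (n > 1) stats::var(scores) else 0),
            class = "logrank_scores")
}

#' Two-sample log-rank statistic
#'
#' Standardized log-rank statistic between the two groups defined by
#' `membership`: the sum over pooled event times of observed minus expected
#' events in group 1, divided by the square root of the hypergeometric
#' variance. The squared statistic is the usual chi-squared form maximized by
#' the log-rank split rule.
#'
#' @param time Observed times.
#' @param event Event indicators (1 = event).
#' @param membership Logical (or 0/1) group-1 indicator; both groups must be
#'   non-empty.
#' @return The signed standardized statistic (group 1 minus expected).
#' @export
logrank_statistic <- function(time, event, membership) {
  g <- as.logical(membership)
  if (!any(g) || all(g)) stop("both groups must be non-empty")
  if (sum(event) == 0)
    stop(structure(class = c("undefined_statistic", "error", "condition"),
                   list(message = "log-rank statistic undefined: no events",
                        call = sys.call(-1))))
  dt <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (s in dt) {
    at <- time >= s
    N_t <- sum(at)
    n1 <- sum(at & g)
    d <- sum(time == s & event == 1)
    d1 <- sum(time == s & event == 1 & g)
    U <- U + d1 - d * n1 / N_t
    if (N_t > 1)
      V <- V + d * (n1 / N_t) * (1 - n1 / N_t) * (N_t - d) / (N_t - 1)
  }
  if (V <= 0)
    stop(structure(class = c("undefined_statistic", "error", "condition"),
                   list(message = "log-rank statistic undefined: zero variance",
                        call = sys.call(-1))))
  U / sqrt(V)
}

#' Log-rank-score split statistic
#'
#' The standardized sum of log-rank scores in the proposed left child:
#' |sum_left(a_j) - R1 * abar| / sqrt(R1 (1 - R1/N) S_a^2), where abar and
#' S_a^2 are the mean and sample variance of the node's scores and R1 the
#' left-child size. The best split maximizes this absolute statistic.
#'
#' @param scores A [logrank_scores()] object or a numeric score vector.
#' @param x Covariate values (numeric/ordered, or factor).
#' @param split_set For numeric `x` a threshold (left: `x <= split_set`);
#'   for a factor, the subset of levels sent left.
#' @return The absolute standardized statistic.
#' @export
logrank_score_statistic <- function(scores, x, split_set) {
  a <- if (inherits(scores, "logrank_scores")) scores$scores else as.numeric(scores)
  n <- length(a)
  if (length(x) != n) stop("x and scores must have equal length")
  left <- if (is.factor(x) || is.character(x)) as.character(x) %in% split_set
          else x <= split_set
  r1 <- sum(left)
  if (r1 == 0L || r1 == n) stop("improper split: one child is empty")
  abar <- mean(a)
  s2 <- stats::var(a)
  if (!is.finite(s2) || s2 <= 0)
    stop(structure(class = c("undefined_statistic", "error", "condition"),
                   list(message = "log-rank score statistic undefined: zero score variance",
                        call = sys.call(-1))))
  abs(sum(a[left]) - r1 * abar) / sqrt(r1 * (1 - r1 / n) * s2)
}

#' Permutation-framework linear rank test of covariate-outcome association
#'
#' Tests independence of one covariate and the log-rank score transformation
#' of the outcome. For a categorical covariate the linear statistic of
#' per-level score sums is standardized by its exact conditional
#' (permutation) mean and covariance and summarized as a quadratic form with
#' a chi-squared reference distribution (df = levels - 1; for a binary
#' covariate this is the squared standardized statistic). A numeric covariate
#' with more than two distinct values enters as its own score vector, giving
#' the single-df linear rank statistic. At nodes smaller than `small_n` the
#' p-value is computed by Monte-Carlo permutation of the scores instead of
#' the asymptotic approximation.
#'
#' @param x Covariate values (factor: categorical; numeric: linear).
#' @param scores A [logrank_scores()] object or numeric score vector.
#' @param small_n Node-size threshold below which the Monte-Carlo permutation
#'   p-value is used (default 30).
#' @param n_perm Number of Monte-Carlo permutations (default 9999).
#' @return `NULL` when `x` is constant (no admissible test); otherwise a list
#'   with `statistic` (quadratic form), `df`, and `p_value`.
#' @export
linear_rank_test <- function(x, scores, small_n = 30L, n_perm = 9999L) {
  a <- if (inherits(scores, "logrank_scores")) scores$scores else as.numeric(scores)
  n <- length(a)
  s2 <- stats::var(a)
  if (!is.finite(s2) || s2 <= 0) return(NULL)
  if (is.numeric(x) && length(unique(x)) > 2L) {
    # continuous/ordered covariate: single-df linear statistic with x as scores
    sx <- sum((x - mean(x))^2)
    if (sx <= 0) return(NULL)
    m <- 1L
    quad <- function(av) (sum(x * av) - n * mean(x) * mean(av))^2 /
      (sx * stats::var(av))
  } else {
    f <- droplevels(factor(x))
    L <- nlevels(f)
    if (L < 2L) return(NULL)
    m <- L - 1L
    nl <- tabulate(f, nbins = L)
    quad <- function(av) {
      Tl <- vapply(seq_len(m), function(l) sum(av[as.integer(f) == l]), 0)
      z <- Tl - nl[seq_len(m)] * mean(av)
      M <- stats::var(av) * (diag(nl[seq_len(m)], m) -
                               outer(nl[seq_len(m)], nl[seq_len(m)]) / n)
      drop(crossprod(z, solve(M, z)))
    }
  }
  stat <- quad(a)
  p <- if (n < small_n) {
    hits <- sum(vapply(seq_len(n_perm),
                       function(b) quad(sample(a)) >= stat - 1e-12, TRUE))
    (1 + hits) / (1 + n_perm)
  } else {
    stats::pchisq(stat, df = m, lower.tail = FALSE)
  }
  list(statistic = unname(stat), df = m, p_value = unname(p))
}

#' Conditional-inference variable selection at a node
#'
#' Runs the linear rank test of every candidate covariate against the node's
#' log-rank scores, Bonferroni-adjusts the p-values over the number of
#' testable (non-constant) covariates, and selects the minimum adjusted-p
#' covariate if its adjusted p-value is at most `alpha`; otherwise signals a
#' stop (the node becomes terminal).
#'
#' @param data A `surv_data` object (the node's subjects).
#' @param alpha Significance level for the stopping rule (default 0.05).
#' @param vars Covariate names to test (default all).
#' @inheritParams linear_rank_test
#' @return A list with `stop` (logical), `variable` (selected name or `NA`),
#'   and `tests`, a data.frame of per-covariate statistics, raw and adjusted
#'   p-values.
#' @export
select_split_variable <- function(data, alpha = 0.05,
                                  vars = names(data$covariates),
                                  small_n = 30L, n_perm = 9999L) {
  sc <- logrank_scores(data$time, data$event)
  res <- lapply(vars, function(v)
    linear_rank_test(data$covariates[[v]], sc, small_n, n_perm))
  keep <- !vapply(res, is.null, TRUE)
  if (!any(keep))
    return(list(stop = TRUE, variable = NA_character_,
                tests = data.frame(variable = character(0))))
  m <- sum(keep)
  tests <- data.frame(
    variable = vars[keep],
    statistic = vapply(res[keep], `[[`, 0, "statistic"),
    df = vapply(res[keep], `[[`, 0, "df"),
    p_value = vapply(res[keep], `[[`, 0, "p_value"))
  tests$adjusted_p <- pmin(1, tests$p_value * m)
  # select on the raw p-value (the adjustment only gates stopping; capped
  # adjusted values would tie at 1 and bias selection to column order)
  best <- which.min(tests$p_value)
  if (tests$adjusted_p[best] > alpha)
    return(list(stop = TRUE, variable = NA_character_, tests = tests))
  list(stop = FALSE, variable = tests$variable[best], tests = tests)
}
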