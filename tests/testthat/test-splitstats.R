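test_that("log-rank scores match the hand-computed fixture and sum to zero", {
  sc <- logrank_scores(c(1, 2, 3), c(1, 1, 1))
  expect_equal(sc$scores, c(2/3, 1/6, -5/6))
  expect_equal(sum(sc$scores), 0)
  expect_equal(sc$ranks, 1:3)

  # single censored subject: empty event sum
  expect_equal(logrank_scores(2.5, 0L)$scores, 0)
  expect_error(logrank_scores(c(-1, 2), c(1, 1)), "non-negative")

  # telescoping-sum property over random uncensored inputs
  set.seed(31)
  for (r in 1:25) {
    n <- sample(2:40, 1)
    tm <- sample(1000, n)   # distinct times
    expect_equal(sum(logrank_scores(tm, rep(1L, n))$scores), 0,
                 tolerance = 1e-12)
  }
})

test_that("the two-sample log-rank statistic matches survdiff and is rank-based", {
  # identical survival experience in both groups
  expect_equal(logrank_statistic(c(1, 2, 1, 2), c(1, 1, 1, 1),
                                 c(TRUE, TRUE, FALSE, FALSE)), 0)
  # hand-checkable fixture: early events in group A, late in group B
  s <- logrank_statistic(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(s, (7/6) / sqrt(17/36))

  set.seed(17)
  for (r in 1:20) {
    n <- sample(10:60, 1)
    tm <- rexp(n); ev <- rbinom(n, 1, 0.7); g <- rbinom(n, 1, 0.5)
    if (sum(ev) == 0 || length(unique(g)) < 2) next
    ours <- tryCatch(logrank_statistic(tm, ev, g), error = function(e) NULL)
    if (is.null(ours)) next
    sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(ours^2, unname(sd$chisq), tolerance = 1e-8)
    # invariance under strictly monotone time transformation
    expect_equal(logrank_statistic(exp(tm), ev, g), ours, tolerance = 1e-10)
  }

  expect_error(logrank_statistic(c(1, 2), c(0, 0), c(TRUE, FALSE)),
               class = "undefined_statistic")
  expect_error(logrank_statistic(c(1, 2), c(1, 1), c(TRUE, TRUE)), "non-empty")
})

test_that("the log-rank-score split statistic matches its formula", {
  sc <- logrank_scores(c(1, 2, 3), c(1, 1, 1))
  # left child = the subject with time 1; abar = 0, S^2 = 7/12
  expect_equal(logrank_score_statistic(sc, c(1, 2, 3), split_set = 1.5),
               (2/3) / sqrt(1 * (1 - 1/3) * 7/12))
  expect_error(logrank_score_statistic(sc, c(1, 2, 3), split_set = 10),
               "improper")
  # relabeling invariance: permuting subjects together with x
  set.seed(4)
  tm <- rexp(20); ev <- rbinom(20, 1, 0.8); x <- rnorm(20)
  sc2 <- logrank_scores(tm, ev)
  i1 <- logrank_score_statistic(sc2, x, 0)
  p <- sample(20)
  i2 <- logrank_score_statistic(logrank_scores(tm[p], ev[p])$scores, x[p], 0)
  expect_equal(i1, i2, tolerance = 1e-10)
})

test_that("the linear rank test detects association and respects invariances", {
  set.seed(21)
  tm <- rexp(100); ev <- rep(1L, 100)
  sc <- logrank_scores(tm, ev)
  x_strong <- as.integer(rank(tm) <= 50)   # earliest-event half
  res <- linear_rank_test(x_strong, sc)
  expect_lt(res$p_value, 1e-3)
  # functional invariance: duplicated covariate gives the identical result
  expect_identical(linear_rank_test(x_strong, sc), res)
  # constant covariate is excluded from testing
  expect_null(linear_rank_test(rep(1, 100), sc))
  # numeric covariates give the single-df linear statistic
  expect_equal(linear_rank_test(rnorm(100), sc)$df, 1L)
  expect_equal(linear_rank_test(factor(sample(letters[1:5], 100, TRUE)), sc)$df,
               4L)
})

test_that("variable selection picks the strong covariate and stops under the null", {
  d <- resolve_design(strong_binary_design(n = 250))
  hits <- vapply(1:20, function(r) {
    dat <- gen_dataset(d, seed = 700 + r)
    sel <- select_split_variable(dat, alpha = 0.05)
    !sel$stop && sel$variable == "x1"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_true(all(c("p_value", "adjusted_p") %in%
                    names(select_split_variable(gen_dataset(d, 1))$tests)))
})

test_that("Kaplan-Meier estimates match the product-limit form and survfit", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(eval_curve(km, c(0.5, 1, 2.5, 9)), c(1, 2/3, 1/3, 0))
  # no events: flat at 1
  expect_equal(eval_curve(kaplan_meier(c(1, 2), c(0, 0)), c(0, 5)), c(1, 1))
  # scale invariance: doubling every subject leaves the curve unchanged
  set.seed(12)
  tm <- rexp(30); ev <- rbinom(30, 1, 0.6)
  k1 <- kaplan_meier(tm, ev)
  k2 <- kaplan_meier(rep(tm, 2), rep(ev, 2))
  expect_equal(k1$surv, k2$surv)
  # independent oracle: survival::survfit
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(eval_curve(k1, sf$time), sf$surv, tolerance = 1e-10)
})

test_that("surv_curve objects validate and evaluate right-continuously", {
  cv <- surv_curve(c(1, 2), c(0.6, 0.2))
  expect_equal(eval_curve(cv, c(0.99, 1, 1.5, 2, 3)), c(1, 0.6, 0.6, 0.2, 0.2))
  expect_error(surv_curve(c(1, 2), c(0.2, 0.6)), "non-increasing")
  expect_error(surv_curve(c(1, 2), c(1.5, 0.2)), "\\[0, 1\\]")
})
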