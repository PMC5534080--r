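test_that("the censoring survival estimator follows the reverse product-limit", {
  # no censored subjects: G = 1 over the whole range
  expect_equal(eval_curve(censoring_km(c(1, 2, 3), c(1, 1, 1)), c(0, 2, 9)),
               c(1, 1, 1))
  # all subjects censored at distinct times: ordinary product-limit
  G <- censoring_km(c(1, 2, 3), c(0, 0, 0))
  expect_equal(G$surv, c(2/3, 1/3, 0))
  # ties: censorings occur after events, so the event at t does not shrink
  # the censoring at-risk set at t
  Gt <- censoring_km(c(1, 1, 2), c(1, 0, 0))
  expect_equal(Gt$surv[1], 1 - 1/2)

  # IPCW unbiasedness: 1/G weights of observed events average to ~1
  set.seed(61)
  tev <- rexp(4000); cen <- rexp(4000, 0.5)
  tm <- pmin(tev, cen); ev <- as.integer(tev <= cen)
  G2 <- censoring_km(tm, ev)
  t0 <- stats::quantile(tm, 0.5)
  w <- ifelse(tm <= t0 & ev == 1, 1 / eval_curve(G2, tm), 0)
  expect_lt(abs(mean(w) - mean(tev <= t0)), 0.03)
})

test_that("the IPCW Brier score matches hand computations", {
  # perfect oracle predictions, no censoring: BS = 0
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1)
  G1 <- censoring_km(tm, ev)
  pred_perfect <- as.numeric(tm > 2.5)
  expect_equal(brier_score(pred_perfect, tm, ev, 2.5, G1), 0)
  # constant 0.5 prediction, no censoring: BS = 0.25 at every t
  for (t0 in c(0.5, 2.5, 3.5))
    expect_equal(brier_score(rep(0.5, 4), tm, ev, t0, G1), 0.25)

  # hand-evaluated censored fixture: times (1,2,3,4), subject 2 censored,
  # G drops to 2/3 at t=2; predictions (.9,.8,.7,.6) at t = 2.5:
  #   subj1 event before t: 0.9^2 / G(1) = 0.81
  #   subj2 censored before t: contributes 0
  #   subj3, subj4 survivors: (1-.7)^2 / (2/3) + (1-.6)^2 / (2/3)
  ev2 <- c(1, 0, 1, 1)
  G2 <- censoring_km(tm, ev2)
  expect_equal(eval_curve(G2, c(1.5, 2)), c(1, 2/3))
  bs <- brier_score(c(0.9, 0.8, 0.7, 0.6), tm, ev2, 2.5, G2)
  expect_equal(bs, (0.81 + 0 + 0.09 * 1.5 + 0.16 * 1.5) / 4)

  # with no censoring the IPCW score reduces exactly to the plain Brier score
  set.seed(5)
  p <- runif(50); tmr <- rexp(50)
  plain <- mean((p - as.numeric(tmr > 1))^2)
  expect_equal(brier_score(p, tmr, rep(1L, 50), 1,
                           censoring_km(tmr, rep(1L, 50))), plain)
})

test_that("integrated Brier scores are normalized trapezoid integrals", {
  grid <- c(0.5, 1, 2, 4)
  expect_equal(integrated_brier(rep(0.25, 4), grid), 0.25)
  expect_equal(integrated_brier(rep(0, 4), grid), 0)
  # piecewise-linear toy curve, hand trapezoid:
  # segments (.5: .1 -> 1: .2), (1: .2 -> 2: .1), (2: .1 -> 4: .3)
  bs <- c(0.1, 0.2, 0.1, 0.3)
  hand <- (0.5 * 0.15 + 1 * 0.15 + 2 * 0.2) / 3.5
  expect_equal(integrated_brier(bs, grid), hand)
  expect_error(integrated_brier(0.2, 3), "two points")
})

test_that("the .632+ bootstrap behaves as its algebra dictates", {
  d <- resolve_design(get_design("binary2"))
  dat <- gen_dataset(d, seed = 71)
  # covariate-free KM model: no overfitting, R ~ 0, estimate ~ apparent
  rep_km <- boot632plus(list(km = km_model()), dat, B = 5L, seed = 31)$km
  expect_lt(abs(rep_km$ibs632 - rep_km$ibs_app), 0.02)
  # determinism
  rep_km2 <- boot632plus(list(km = km_model()), dat, B = 5L, seed = 31)$km
  expect_identical(rep_km, rep_km2)

  # the combined curve is a convex combination of the apparent error and the
  # (no-information-capped) out-of-bag error, so it lies between them and
  # never exceeds the no-information error
  reps <- boot632plus(standard_models(n_trees = 30L), dat, B = 5L, seed = 32)
  for (r in reps) {
    err1 <- pmin(r$bs_boot, r$bs_noinf)
    expect_true(all(r$bs632 >= pmin(r$bs_app, err1) - 1e-9))
    expect_true(all(r$bs632 <= pmax(r$bs_app, err1) + 1e-9))
    expect_true(all(r$bs632 <= pmax(r$bs_app, r$bs_noinf) + 1e-9))
    expect_true(all(r$bs632 >= 0))
    expect_lt(r$ibs632, 0.5)   # far from the coin-toss uselessness bound
  }
})

test_that("the benchmark table has one row per design-model-repetition", {
  expect_equal(nrow(benchmark_repetitions(list("binary2"), list(), 2L)), 0L)
  mods <- list(km = km_model())
  res <- benchmark_repetitions(list("binary1", "binary2"), mods, n_reps = 2L,
                               B = 2L, seed = 77)
  expect_equal(nrow(res), 4L)
  expect_setequal(res$design, c("binary1", "binary2"))
  # per-cell seeds make rows reproducible in isolation
  res2 <- benchmark_repetitions(list("binary2"), mods, n_reps = 2L, B = 2L,
                                seed = 77)
  expect_equal(res$ibs[res$design == "binary2"], res2$ibs)
})

test_that("evaluation grids avoid the unstable censoring tail", {
  set.seed(9)
  tev <- rexp(300); cen <- rexp(300, 0.7)
  tm <- pmin(tev, cen); ev <- as.integer(tev <= cen)
  G <- censoring_km(tm, ev)
  grid <- eval_time_grid(tm, ev, G)
  expect_lte(length(grid), 64L)
  expect_true(all(eval_curve(G, grid) > 0))
  expect_lte(max(grid), stats::quantile(tm, 0.95))
})
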