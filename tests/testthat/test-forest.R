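test_that("bootstrap bookkeeping matches sampling-with-replacement theory", {
  d <- resolve_design(get_design("binary2"))
  dat <- gen_dataset(d, seed = 21)
  f <- fit_rsf(dat, "logrank", n_trees = 60L, seed = 13)
  expect_equal(colSums(f$inbag), rep(100, 60))  # in-bag size N per tree
  # per-tree OOB fraction concentrates near e^-1
  expect_lt(abs(mean(colMeans(f$oob)) - exp(-1)), 0.02)
  expect_error(fit_rsf(dat, "cif"), "arg")
  # determinism: same seed, identical forests
  f2 <- fit_rsf(dat, "logrank", n_trees = 60L, seed = 13)
  expect_identical(lapply(f$trees, `[[`, "split_var"),
                   lapply(f2$trees, `[[`, "split_var"))
  expect_identical(f$inbag, f2$inbag)
})

test_that("degenerate forests reduce to the marginal estimate", {
  set.seed(3)
  dat <- rand_surv_data(60)
  grid <- eval_time_grid(dat$time, dat$event)
  f <- fit_rsf(dat, "logrank", n_trees = 1L, min_node_size = 100L, seed = 5)
  p <- predict_survival(f, dat, grid)
  # single root-only tree: prediction is the in-bag Nelson-Aalen survival,
  # identical for every subject
  expect_equal(p[1, ], p[33, ])
  bag <- which(f$inbag[, 1] > 0)
  bag_idx <- rep(bag, f$inbag[bag, 1])
  expect_equal(p[1, ],
               exp(-survforests:::nelson_aalen(dat$time[bag_idx],
                                               dat$event[bag_idx], grid)),
               tolerance = 1e-10)

  # averaging idempotence: a forest of duplicated identical trees predicts
  # exactly like the single tree
  fdup <- f
  fdup$trees <- rep(f$trees, 5)
  fdup$n_trees <- 5L
  fdup$inbag <- f$inbag[, rep(1, 5)]
  fdup$oob <- f$oob[, rep(1, 5)]
  fdup$train_terms <- f$train_terms[, rep(1, 5)]
  expect_equal(predict_survival(fdup, dat, grid), p)
})

test_that("ensemble predictions are proper survival curves ordered by risk", {
  d <- resolve_design(strong_binary_design(n = 300, beta = -3))
  dat <- gen_dataset(d, seed = 11)
  grid <- eval_time_grid(dat$time, dat$event)
  for (f in list(fit_rsf(dat, "logrank", n_trees = 40L, seed = 2),
                 fit_rsf(dat, "logrank_score", n_trees = 40L, seed = 2),
                 fit_cif(dat, n_trees = 40L, seed = 2))) {
    p <- predict_survival(f, dat, grid)
    expect_true(all(p >= -1e-9 & p <= 1 + 1e-9))
    expect_true(all(apply(p, 1, function(r) all(diff(r) <= 1e-9))))
    # beta = -3 lowers the hazard for x1 = 1: that group must survive longer
    g1 <- dat$covariates$x1 == 1
    mid <- which.min(abs(grid - stats::median(dat$time)))
    expect_gt(mean(p[g1, mid]), mean(p[!g1, mid]))
  }
})

test_that("out-of-bag predictions cover subjects and behave honestly", {
  set.seed(44)
  dat <- rand_surv_data(80, censor_frac = 0.25)
  grid <- eval_time_grid(dat$time, dat$event)
  f <- fit_rsf(dat, "logrank", n_trees = 100L, seed = 3)
  # coverage probability 1 - 0.632^n_trees is ~1 at 100 trees
  oobp <- oob_predict(f, grid)
  expect_false(anyNA(oobp))
  # a subject in-bag in every tree is flagged and excluded
  f2 <- f
  f2$oob[5, ] <- FALSE
  expect_warning(p2 <- oob_predict(f2, grid), "no contributing trees")
  expect_true(all(is.na(p2[5, ])))
  expect_false(anyNA(p2[-5, ]))
  # optimism: OOB error is no better than apparent error on null-signal data
  G <- censoring_km(dat$time, dat$event)
  ibs <- function(p) integrated_brier(
    brier_curve(p, dat$time, dat$event, grid, G), grid)
  expect_gte(ibs(oobp) + 1e-6, ibs(predict_survival(f, dat, grid)))
})

test_that("permutation importance ranks the dominant covariate first", {
  d <- resolve_design(sim_design("vimp", 300,
    covariates = c(list(covariate_spec("strong", "binary", bernoulli_p = 0.5,
                                       coefficient = -2.5)),
                   lapply(1:4, function(j)
                     covariate_spec(paste0("noise", j), "binary",
                                    bernoulli_p = 0.5, coefficient = 0))),
    event_shape = 1, intercept = 0, censor_shape = 1,
    target_censoring = 0.2, hazard_trend = "constant"))
  dat <- gen_dataset(d, seed = 15)
  f <- fit_rsf(dat, "logrank", n_trees = 60L, mtry = 5L, seed = 4)
  vi <- permutation_vimp(f, n_perm = 2L, seed = 99)
  expect_equal(vi$variable[vi$rank == 1], "strong")
  expect_gt(vi$importance[vi$variable == "strong"],
            3 * max(abs(vi$importance[vi$variable != "strong"])))
})

test_that("CIF forests subsample without replacement and reduce to the KM", {
  set.seed(9)
  dat <- rand_surv_data(70, censor_frac = 0.25)
  grid <- eval_time_grid(dat$time, dat$event)
  f <- fit_cif(dat, n_trees = 30L, seed = 8)
  expect_true(all(colSums(f$inbag) == ceiling(0.632 * 70)))
  expect_true(all(f$inbag %in% 0:1))
  f2 <- fit_cif(dat, n_trees = 30L, seed = 8)
  expect_equal(predict_survival(f, dat, grid), predict_survival(f2, dat, grid))

  # full-sample root-only CIF: the weighted KM is the ordinary KM
  expect_warning(froot <- fit_cif(dat, n_trees = 1L, min_node_size = 200L,
                                  subsample_fraction = 1, seed = 1),
                 "out-of-bag")
  proot <- predict_survival(froot, dat, grid)
  expect_equal(proot[1, ], eval_curve(kaplan_meier(dat$time, dat$event), grid),
               tolerance = 1e-10)
})

test_that("CIF and RSF agree closely on a strong binary-signal fixture", {
  d <- resolve_design(strong_binary_design(n = 300, beta = -3))
  dat <- gen_dataset(d, seed = 19)
  grid <- eval_time_grid(dat$time, dat$event)
  pr <- predict_survival(fit_rsf(dat, "logrank", n_trees = 60L, seed = 2),
                         dat, grid)
  pc <- predict_survival(fit_cif(dat, n_trees = 60L, seed = 2), dat, grid)
  expect_lt(mean(apply(abs(pr - pc), 1, max)), 0.1)
})

test_that("OOB error stabilizes as the ensemble grows", {
  d <- resolve_design(get_design("binary2"))
  dat <- gen_dataset(d, seed = 33)
  grid <- eval_time_grid(dat$time, dat$event)
  G <- censoring_km(dat$time, dat$event)
  ibs_at <- vapply(c(50L, 100L, 150L), function(nt) {
    f <- fit_rsf(dat, "logrank", n_trees = nt, seed = 6)
    integrated_brier(brier_curve(oob_predict(f, grid), dat$time, dat$event,
                                 grid, G), grid)
  }, 0)
  expect_lt(abs(ibs_at[3] - ibs_at[2]) / ibs_at[2], 0.10)
})
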