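test_that("covariate sampling matches the design distributions", {
  set.seed(101)
  specs <- binary_family_params("decreasing")$beta
  spec_list <- lapply(seq_along(specs), function(j)
    covariate_spec(paste0("x", j), "binary", bernoulli_p = 0.5,
                   coefficient = specs[j]))
  X <- sample_covariates(spec_list, 1000L)
  expect_equal(dim(X), c(1000L, 10L))
  expect_true(all(unlist(X) %in% c(0, 1)))
  # binomial sampling bound: 3 * sqrt(p(1-p)/n)
  expect_true(all(abs(colMeans(X) - 0.5) < 3 * sqrt(0.25 / 1000)))

  ps <- covariate_spec("z", "polytomous", levels = paste0("c", 1:4),
                       coefficient = rep(0, 4))
  Z <- sample_covariates(list(ps), 4000L)
  freq <- table(Z$z) / 4000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))

  expect_error(sample_covariates(list(), 10), "empty")
  expect_error(covariate_spec("x", "binary", bernoulli_p = 1, coefficient = 0),
               "bernoulli_p")
  expect_error(covariate_spec("z", "polytomous", levels = c("a", "b"),
                              coefficient = c(0, 0)), "3 levels")
})

test_that("the linear-predictor Weibull scale follows the PH parameterization", {
  d0 <- sim_design("null", 5,
                   covariates = list(covariate_spec("x", "binary",
                                                    bernoulli_p = 0.5,
                                                    coefficient = 0)),
                   event_shape = 1, intercept = 0, censor_shape = 1,
                   target_censoring = 0.2, hazard_trend = "constant")
  X <- data.frame(x = c(0, 1, 0))
  expect_equal(linear_predictor_scale(d0, X), rep(1, 3))

  d1 <- sim_design("const", 5, d0$covariates, event_shape = 1,
                   intercept = 0.9, censor_shape = 1,
                   target_censoring = 0.2, hazard_trend = "constant")
  expect_equal(linear_predictor_scale(d1, data.frame(x = 0)), exp(-0.9))

  d2 <- sim_design("dec", 5,
                   list(covariate_spec("x", "binary", bernoulli_p = 0.5,
                                       coefficient = 0.5)),
                   event_shape = 0.8, intercept = -0.98, censor_shape = 0.4,
                   target_censoring = 0.5, hazard_trend = "decreasing")
  expect_equal(linear_predictor_scale(d2, data.frame(x = 1)),
               exp(0.98 / 0.8 - 0.5 / 0.8))
  expect_error(linear_predictor_scale(d2, data.frame(y = 1)), "missing")
})

test_that("event-time inversion gives Weibull times with the stated shape", {
  d <- sim_design("exp", 5,
                  list(covariate_spec("x", "binary", bernoulli_p = 0.5,
                                      coefficient = 0)),
                  event_shape = 1, intercept = 0, censor_shape = 1,
                  target_censoring = 0.2, hazard_trend = "constant")
  # deterministic inverse transform: U = exp(-1), shape 1, scale 1 -> T = 1
  expect_equal(gen_event_times(d, lambda = 1, u = exp(-1)), 1)

  set.seed(7)
  tt <- gen_event_times(d, lambda = rep(1, 50000))
  expect_lt(abs(mean(tt) - 1), 3 / sqrt(50000))

  # shape 0.8: decreasing hazard, i.e. the Nelson-Aalen slope falls with t
  dw <- sim_design("dec", 5, d$covariates, event_shape = 0.8, intercept = 0,
                   censor_shape = 1, target_censoring = 0.2,
                   hazard_trend = "decreasing")
  set.seed(8)
  tw <- gen_event_times(dw, lambda = rep(1, 50000))
  H <- function(t) -log(mean(tw > t))
  slope_early <- (H(0.5) - H(0.1)) / 0.4
  slope_late <- (H(2) - H(1)) / 1
  expect_gt(slope_early, slope_late)
})

test_that("censoring calibration hits its target rate", {
  d <- get_design("binary2")  # 50% censoring, decreasing hazard
  scale <- calibrate_censoring(d, n_probe = 10000L, tolerance = 0.02)
  d$censor_scale <- scale
  dat <- gen_dataset(d, seed = 303, n = 10000L)
  expect_lt(abs(mean(dat$event == 0) - 0.5), 0.02)

  d0 <- d
  d0$target_censoring <- 0
  expect_identical(calibrate_censoring(d0), Inf)
  d0$censor_scale <- NA_real_
  dat0 <- gen_dataset(d0, seed = 9)
  expect_true(all(dat0$event == 1L))
})

test_that("generated datasets are reproducible and internally consistent", {
  d <- resolve_design(get_design("binary2"))
  a <- gen_dataset(d, seed = 42)
  b <- gen_dataset(d, seed = 42)
  expect_identical(a, b)
  expect_equal(n_subjects(a), 100L)
  expect_equal(ncol(a$covariates), 10L)
  expect_lt(abs(mean(a$event == 0) - 0.5), 0.20)  # n = 100, wide MC band
  # observed-time decomposition holds exhaustively
  expect_equal(a$time, pmin(a$latent_event, a$latent_censor))
  expect_identical(a$event, as.integer(a$latent_event <= a$latent_censor))
})

test_that("the built-in registry reproduces the table of study designs", {
  reg <- builtin_designs()
  expect_length(reg, 22L)
  fam <- function(prefix) reg[grep(prefix, names(reg))]
  expect_setequal(vapply(fam("^binary"), `[[`, 0L, "n"),
                  c(100L, 100L, 250L, 1000L, 1500L, 2000L))
  expect_setequal(vapply(fam("^interact"), `[[`, 0L, "n"),
                  c(100L, 100L, 1000L, 1500L))
  expect_length(fam("^poly"), 6L)
  expect_length(fam("^mixed"), 6L)
  # hazard trend consistent with the event shape in every design
  for (d in reg) {
    implied <- if (d$event_shape > 1) "increasing" else
      if (d$event_shape < 1) "decreasing" else "constant"
    expect_identical(d$hazard_trend, implied)
  }
  # binary decreasing-hazard family carries the printed parameters
  d2 <- reg[["binary2"]]
  expect_equal(d2$event_shape, 0.8)
  expect_equal(d2$intercept, -0.98)
  expect_equal(d2$censor_shape, 0.4)
  expect_equal(vapply(d2$covariates, `[[`, 0, "coefficient")[5], -2)
  expect_error(get_design("nope"), "unknown design")
})

test_that("CSV round-trips preserve the dataset byte-for-byte", {
  d <- resolve_design(get_design("mixed2"))
  dat <- gen_dataset(d, seed = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_survival_csv(dat, f1)
  write_survival_csv(gen_dataset(d, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_survival_csv(f1)
  expect_equal(back$time, dat$time)
  expect_identical(back$event, dat$event)
  expect_equal(as.character(back$covariates$z1), as.character(dat$covariates$z1))
  unlink(c(f1, f2))
})
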