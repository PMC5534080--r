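#' Evaluation time grid for Brier score curves
#'
#' Unique event times, truncated at the `q`-th quantile of follow-up and at
#' times where the censoring survival estimate G is positive, thinned to at
#' most `max_points` quantile-spaced points. Truncation keeps the inverse
#' weights 1/G away from instability near the end of follow-up.
#'
#' @param time Observed times.
#' @param event Event indicators.
#' @param G Optional censoring [surv_curve()] (default computed from the
#'   data).
#' @param max_points Maximum grid size (default 64).
#' @param q Follow-up quantile at which to truncate (default 0.95).
#' @return Increasing numeric grid with at least two points.
#' @export
eval_time_grid <- function(time, event, G = NULL, max_points = 64L,
                           q = 0.95) {
  if (is.null(G)) G <- censoring_km(time, event)
  grid <- sort(unique(time[event == 1]))
  if (length(grid) < 2L) grid <- sort(unique(time))
  cap <- stats::quantile(time, q, names = FALSE)
  grid <- grid[grid <= cap & eval_curve(G, grid) > 0]
  if (length(grid) < 2L) grid <- sort(unique(time))[1:2]
  if (length(grid) > max_points)
    grid <- unique(grid[round(seq(1L, length(grid), length.out = max_points))])
  grid
}

ipcw_weights <- function(time, event, t, G) {
  Gt_i <- eval_curve(G, time)
  w_event <- ifelse(time <= t & event == 1, 1 / Gt_i, 0)
  w_alive <- as.numeric(time > t) / eval_curve(G, t)
  list(w_event = w_event, w_alive = w_alive)
}

#' IPCW Brier score at one time point
#'
#' BS(t) = mean over test subjects of
#' S(t|x)^2 I(T <= t, event)/G(T) + (1-S(t|x))^2 I(T > t)/G(t),
#' the inverse-probability-of-censoring-weighted squared prediction error.
#' Subjects censored before t contribute nothing. With no censoring (G = 1)
#' this reduces exactly to the uncensored Brier score.
#'
#' @param pred Predicted survival probabilities S(t|x), one per subject.
#' @param time,event Observed test outcomes.
#' @param t Evaluation time.
#' @param G Censoring [surv_curve()] (from [censoring_km()]).
#' @return The Brier score at `t`.
#' @export
brier_score <- function(pred, time, event, t, G) {
  if (eval_curve(G, t) <= 0)
    stop("censoring survival G is zero at t = ", t, "; truncate the grid")
  w <- ipcw_weights(time, event, t, G)
  keep <- !is.na(pred)
  mean(pred[keep]^2 * w$w_event[keep] + (1 - pred[keep])^2 * w$w_alive[keep])
}

#' IPCW Brier score curve over a grid
#'
#' @param pred Matrix of predicted survival probabilities (subjects by grid
#'   points), as returned by [predict_survival()].
#' @param time,event Observed test outcomes.
#' @param grid Evaluation times (matching the prediction columns).
#' @param G Censoring [surv_curve()].
#' @return Numeric vector BS(t) over the grid.
#' @export
brier_curve <- function(pred, time, event, grid, G) {
  if (ncol(pred) != length(grid)) stop("prediction columns must match the grid")
  vapply(seq_along(grid), function(j)
    brier_score(pred[, j], time, event, grid[j], G), 0)
}

#' Integrated Brier score
#'
#' Trapezoidal integral of the Brier score curve over the grid, divided by
#' the grid span, so the result is unitless in \[0, 1\] and comparable across
#' follow-up lengths (a useless constant prediction of 0.5 scores 0.25; 0.5
#' is the coin-toss uselessness bound on the score scale).
#'
#' @param bs Brier score curve values.
#' @param grid Evaluation times (length >= 2, increasing).
#' @return The normalized integrated Brier score.
#' @export
integrated_brier <- function(bs, grid) {
  if (length(grid) < 2L) stop("the evaluation grid needs at least two points")
  if (length(bs) != length(grid)) stop("bs and grid must match")
  h <- diff(grid)
  sum(h * (bs[-1] + bs[-length(bs)]) / 2) / (grid[length(grid)] - grid[1])
}

no_information_curve <- function(pred, time, event, grid, G) {
  vapply(seq_along(grid), function(j) {
    w <- ipcw_weights(time, event, grid[j], G)
    keep <- !is.na(pred[, j])
    mean(pred[keep, j]^2) * mean(w$w_event) +
      mean((1 - pred[keep, j])^2) * mean(w$w_alive)
  }, 0)
}

#' .632+ bootstrap cross-validated prediction error
#'
#' For each of `B` bootstrap samples every model is refitted on the in-bag
#' subjects and scored on the out-of-bag subjects; the out-of-bag error
#' curve, the apparent (resubstitution) error curve and the no-information
#' error (every prediction scored against every outcome) are combined into
#' the .632+ estimate with relative overfitting rate R clipped to \[0, 1\].
#' All models share the same bootstrap samples and the same evaluation grid
#' and censoring estimate (computed once from the full data).
#'
#' @param models Named list of model specifications (see [forest_model()]).
#' @param data A `surv_data`.
#' @param B Number of bootstrap samples (default 5).
#' @param eval_grid Evaluation times; default [eval_time_grid()] of the data.
#' @param seed Integer seed driving the bootstrap draws and the model fits.
#' @return Named list of `pred_error` reports, one per model, each with the
#'   apparent, out-of-bag, no-information and .632+ error curves and the
#'   integrated Brier scores `ibs_app` and `ibs632` (the cross-validated
#'   estimate).
#' @export
boot632plus <- function(models, data, B = 5L, eval_grid = NULL, seed = 1L) {
  if (B < 1L) stop("B must be at least 1")
  if (is.null(names(models)) && length(models))
    names(models) <- vapply(models, `[[`, "", "label")
  n <- n_subjects(data)
  G <- censoring_km(data$time, data$event)
  if (is.null(eval_grid)) eval_grid <- eval_time_grid(data$time, data$event, G)
  ng <- length(eval_grid)

  set.seed(seed)
  boots <- list()
  while (length(boots) < B) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    # a bootstrap sample whose out-of-bag part has no events cannot be scored
    if (length(oob) == 0L || sum(data$event[oob]) == 0L) next
    boots[[length(boots) + 1L]] <- list(idx = idx, oob = oob)
  }
  fit_seeds <- sample.int(.Machine$integer.max, B + 1L)

  out <- lapply(seq_along(models), function(mi) {
    mod <- models[[mi]]
    fit_full <- mod$fit(data, seed = fit_seeds[1] %% 1000000L + mi)
    pred_app <- mod$predict(fit_full, data, eval_grid)
    err_app <- brier_curve(pred_app, data$time, data$event, eval_grid, G)
    err_noinf <- no_information_curve(pred_app, data$time, data$event,
                                      eval_grid, G)
    sum_bs <- rep(0, ng); n_oob_total <- 0
    for (b in seq_len(B)) {
      tr <- subset_surv(data, boots[[b]]$idx)
      te <- subset_surv(data, boots[[b]]$oob)
      fit_b <- mod$fit(tr, seed = fit_seeds[b + 1L] %% 1000000L + mi)
      pred_b <- mod$predict(fit_b, te, eval_grid)
      bs_b <- brier_curve(pred_b, te$time, te$event, eval_grid, G)
      w_b <- length(boots[[b]]$oob)
      sum_bs <- sum_bs + w_b * bs_b
      n_oob_total <- n_oob_total + w_b
    }
    err_boot <- sum_bs / n_oob_total
    err1 <- pmin(err_boot, err_noinf)
    denom <- err_noinf - err_app
    R <- ifelse(denom > 0, (err1 - err_app) / denom, 0)
    R <- pmin(pmax(R, 0), 1)
    w <- 0.632 / (1 - 0.368 * R)
    err632 <- (1 - w) * err_app + w * err1
    structure(list(model_id = names(models)[mi], times = eval_grid,
                   bs_app = err_app, bs_boot = err_boot,
                   bs_noinf = err_noinf, bs632 = err632,
                   ibs_app = integrated_brier(err_app, eval_grid),
                   ibs632 = integrated_brier(err632, eval_grid),
                   estimator = "boot632plus", B = B, n_test = n,
                   seed = seed),
              class = "pred_error")
  })
  names(out) <- names(models)
  out
}

#' @export
print.pred_error <- function(x, ...) {
  cat(sprintf("%s prediction error for '%s' (B=%d, n=%d):\n", x$estimator,
              x$model_id, x$B, x$n_test))
  cat(sprintf("  apparent IBS: %.4f   .632+ IBS: %.4f\n", x$ibs_app, x$ibs632))
  invisible(x)
}

#' Repeated-simulation benchmark of survival forest models
#'
#' For each design and repetition a fresh dataset is generated (per-cell seed
#' derived from `seed`, the design and the repetition, so cells are
#' order-independent and individually reproducible) and every model's .632+
#' bootstrap integrated Brier score is recorded. The long-format result table
#' is sufficient to draw per-design box plots of prediction error by model.
#'
#' @param designs List of [sim_design()] objects or design id strings.
#' @param models Named list of model specifications (see [forest_model()]).
#' @param n_reps Repetitions per design.
#' @param B Bootstrap samples per evaluation (default 5).
#' @param seed Base seed.
#' @return data.frame with columns `design`, `model`, `rep`, `ibs`,
#'   `estimator`, `B`, `seed`, `n`. A repetition that errors is skipped with
#'   a warning; the skipped cells are recorded in `attr(, "failures")` and
#'   the remaining repetitions still run.
#' @export
benchmark_repetitions <- function(designs, models, n_reps, B = 5L,
                                  seed = 1L) {
  if (length(models) == 0L || length(designs) == 0L)
    return(data.frame(design = character(0), model = character(0),
                      rep = integer(0), ibs = numeric(0),
                      estimator = character(0), B = integer(0),
                      seed = integer(0), n = integer(0)))
  designs <- lapply(designs, function(d)
    if (is.character(d)) get_design(d) else d)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "label")
  rows <- list()
  failures <- list()
  for (di in seq_along(designs)) {
    design <- resolve_design(designs[[di]])
    # the cell seed depends on the design's id, not its position, so any
    # subset of cells reruns to identical results
    for (r in seq_len(n_reps)) {
      cell_seed <- derive_seed(seed, id_hash(design$design_id), r)
      cell <- tryCatch({
        dat <- gen_dataset(design, seed = cell_seed)
        reports <- boot632plus(models, dat, B = B, seed = cell_seed)
        lapply(names(reports), function(m) data.frame(
          design = design$design_id, model = m, rep = r,
          ibs = reports[[m]]$ibs632, estimator = "boot632plus",
          B = B, seed = cell_seed, n = design$n))
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- data.frame(
          design = design$design_id, rep = r, seed = cell_seed,
          message = conditionMessage(e))
        list()
      })
      rows <- c(rows, cell)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(design = character(0), model = character(0),
                      rep = integer(0), ibs = numeric(0),
                      estimator = character(0), B = integer(0),
                      seed = integer(0), n = integer(0))
  if (length(failures)) {
    warning(length(failures), " repetition(s) failed and were skipped")
    attr(out, "failures") <- do.call(rbind, failures)
  }
  out
}

id_hash <- function(s) Reduce(function(a, ch) (a * 31 + ch) %% 1000003,
                              utf8ToInt(s), 7)

# Deterministic per-cell seed derivation (counter-based, order-independent).
derive_seed <- function(base, ...) {
  x <- as.double(base) %% 2147483629
  for (k in c(...)) x <- (x * 69069 + as.double(k) * 7919 + 1) %% 2147483629
  as.integer(x) + 1L
}
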