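#' Model specification for the evaluation pipeline
#'
#' Wraps one of the three survival forest models behind the uniform
#' fit/predict interface used by [boot632plus()] and
#' [benchmark_repetitions()]: `"rsf1"` is the random survival forest with the
#' log-rank split rule, `"rsf2"` the log-rank-score variant, `"cif"` the
#' conditional inference forest.
#'
#' @param type `"rsf1"`, `"rsf2"` or `"cif"`.
#' @param n_trees Trees per forest (default 100).
#' @param mtry,min_node_size,min_events Tree-growing controls; `NULL` takes
#'   the per-model defaults of [fit_rsf()] / [fit_cif()].
#' @param alpha,subsample_fraction CIF controls (see [fit_cif()]).
#' @return An object of class `sf_model`: list with `label`, `fit(data,
#'   seed)` and `predict(fit, newdata, times)`.
#' @export
forest_model <- function(type = c("rsf1", "rsf2", "cif"), n_trees = 100L,
                         mtry = NULL, min_node_size = NULL, min_events = NULL,
                         alpha = NULL, subsample_fraction = 0.632) {
  type <- match.arg(type)
  if (type == "cif") {
    if (is.null(mtry)) mtry <- formals(fit_cif)$mtry
    if (is.null(min_node_size)) min_node_size <- formals(fit_cif)$min_node_size
    if (is.null(min_events)) min_events <- formals(fit_cif)$min_events
    if (is.null(alpha)) alpha <- formals(fit_cif)$alpha
  } else {
    if (is.null(min_node_size)) min_node_size <- formals(fit_rsf)$min_node_size
    if (is.null(min_events)) min_events <- formals(fit_rsf)$min_events
  }
  fit <- switch(type,
    rsf1 = function(data, seed) fit_rsf(data, "logrank", n_trees, mtry,
                                        min_node_size, min_events, seed),
    rsf2 = function(data, seed) fit_rsf(data, "logrank_score", n_trees, mtry,
                                        min_node_size, min_events, seed),
    cif = function(data, seed) fit_cif(data, n_trees, alpha, mtry,
                                       subsample_fraction, min_node_size,
                                       min_events, seed))
  structure(list(label = type, fit = fit,
                 predict = function(fit, newdata, times)
                   predict_survival(fit, newdata, times)),
            class = "sf_model")
}

#' Marginal Kaplan-Meier baseline model
#'
#' Ignores all covariates and predicts the training Kaplan-Meier curve for
#' every subject; the covariate-free reference point for prediction error
#' comparisons.
#'
#' @return An `sf_model` specification.
#' @export
km_model <- function() {
  structure(list(
    label = "km",
    fit = function(data, seed) kaplan_meier(data$time, data$event),
    predict = function(fit, newdata, times) {
      n <- if (inherits(newdata, "surv_data")) n_subjects(newdata)
           else nrow(newdata)
      matrix(eval_curve(fit, times), n, length(times), byrow = TRUE)
    }), class = "sf_model")
}

#' The three standard models of the forest comparison
#' @param n_trees Trees per forest (default 100).
#' @param ... Passed to [forest_model()].
#' @return Named list of `sf_model` specs (`rsf1`, `rsf2`, `cif`).
#' @export
standard_models <- function(n_trees = 100L, ...) {
  list(rsf1 = forest_model("rsf1", n_trees = n_trees, ...),
       rsf2 = forest_model("rsf2", n_trees = n_trees, ...),
       cif = forest_model("cif", n_trees = n_trees, ...))
}
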