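fit_forest_engine <- function(data, rule, n_trees, mtry, min_node_size,
                              min_events, alpha, replace, sample_fraction,
                              seed, small_n = 30L, n_perm = 9999L) {
  if (sum(data$event) == 0) stop("data has no events; cannot fit a survival forest")
  if (n_trees < 1L) stop("n_trees must be at least 1")
  n <- n_subjects(data)
  p <- ncol(data$covariates)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  enc <- encode_covariates(data$covariates)
  set.seed(seed)
  size <- if (replace) n else max(1L, ceiling(sample_fraction * n))
  inbag <- matrix(0L, n, n_trees)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, size, replace = replace)
    inbag[, t] <- tabulate(idx, nbins = n)
    trees[[t]] <- grow_tree_cpp(data$time, data$event, enc$X, enc$unordered,
                                idx, forest_rule_code(rule),
                                as.integer(mtry), as.integer(min_node_size),
                                as.integer(min_events), alpha,
                                as.integer(small_n), as.integer(n_perm))
  }
  train_terms <- matrix(0L, n, n_trees)
  for (t in seq_len(n_trees))
    train_terms[, t] <- predict_terminal_cpp(trees[[t]], enc$X)
  structure(list(trees = trees, rule = rule, n_trees = n_trees,
                 inbag = inbag, oob = inbag == 0L,
                 train_terms = train_terms, enc = enc,
                 time = data$time, event = data$event,
                 covariates = data$covariates,
                 params = list(mtry = mtry, min_node_size = min_node_size,
                               min_events = min_events, alpha = alpha,
                               replace = replace,
                               sample_fraction = sample_fraction),
                 seed = seed),
            class = "surv_forest")
}

#' Fit a random survival forest
#'
#' Ensemble of survival trees, each grown on an independent bootstrap sample
#' (size N, with replacement) with per-node random candidate-covariate
#' selection. `rule = "logrank"` gives the classic log-rank split-rule forest
#' (RSF1); `rule = "logrank_score"` the log-rank-score variant (RSF2).
#' Ensemble prediction averages terminal-node Nelson-Aalen cumulative hazards
#' across trees with equal weights.
#'
#' @param data A `surv_data` with at least one event.
#' @param rule `"logrank"` or `"logrank_score"`.
#' @param n_trees Number of trees (default 100).
#' @param mtry Candidate covariates per node; default `ceiling(sqrt(p))`.
#' @param min_node_size,min_events Admissibility constraints per child
#'   (defaults 15 and 3).
#' @param seed Integer seed; fixed seed gives an identical forest.
#' @return An object of class `surv_forest`.
#' @export
fit_rsf <- function(data, rule = c("logrank", "logrank_score"),
                    n_trees = 100L, mtry = NULL, min_node_size = 15L,
                    min_events = 3L, seed = 1L) {
  rule <- match.arg(rule)
  fit_forest_engine(data, rule, n_trees, mtry, min_node_size, min_events,
                    alpha = 1, replace = TRUE, sample_fraction = 1, seed = seed)
}

#' Fit a conditional inference survival forest
#'
#' Ensemble of conditional inference trees (see [grow_ctree()]) fitted on
#' random subsamples drawn without replacement. Prediction uses the weighted
#' Kaplan-Meier estimate over the training set, with per-tree terminal
#' co-membership weights normalized by terminal-node size, so terminals with
#' many subjects at risk carry more weight.
#'
#' The ensemble defaults follow the conditional-forest (as opposed to
#' single-tree) convention: trees are grown to their size limits with no
#' p-value stopping (`alpha = 1`; variable selection is still the
#' Bonferroni-min-p association test), `mtry = 5`, children of at least 7
#' subjects and 1 event, and asymptotic test p-values throughout
#' (`small_n = 0`). Pass `alpha < 1` and `small_n = 30` for ctree-style
#' early-stopped trees as grown by [grow_ctree()].
#'
#' @inheritParams fit_rsf
#' @param alpha Per-node stopping level of the association test (default 1:
#'   no p-value stopping, tree size controlled by the node-size limits).
#' @param subsample_fraction Fraction of subjects sampled without replacement
#'   per tree (default 0.632).
#' @param small_n,n_perm Monte-Carlo permutation settings for small nodes
#'   (defaults 0 and 9999: asymptotic p-values everywhere).
#' @return An object of class `surv_forest` with `rule = "cif"`.
#' @export
fit_cif <- function(data, n_trees = 100L, alpha = 1, mtry = 5L,
                    subsample_fraction = 0.632, min_node_size = 7L,
                    min_events = 1L, seed = 1L, small_n = 0L,
                    n_perm = 9999L) {
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  fit <- fit_forest_engine(data, "cif", n_trees, mtry, min_node_size,
                           min_events, alpha = alpha, replace = FALSE,
                           sample_fraction = subsample_fraction, seed = seed,
                           small_n = small_n, n_perm = n_perm)
  if (subsample_fraction >= 1)
    warning("subsample_fraction = 1: every tree sees all data, no out-of-bag subjects")
  fit
}

#' @export
print.surv_forest <- function(x, ...) {
  lab <- switch(x$rule, logrank = "RSF, log-rank split rule",
                logrank_score = "RSF, log-rank-score split rule",
                cif = "conditional inference forest")
  cat(sprintf("Survival forest (%s): %d trees, %d subjects, %d covariates\n",
              lab, x$n_trees, length(x$time), ncol(x$covariates)))
  invisible(x)
}

new_cov_frame <- function(forest, newdata) {
  if (is.null(newdata)) forest$covariates
  else if (inherits(newdata, "surv_data")) newdata$covariates
  else newdata
}

terminal_ids_matrix <- function(forest, X) {
  out <- matrix(0L, nrow(X), forest$n_trees)
  for (t in seq_len(forest$n_trees))
    out[, t] <- predict_terminal_cpp(forest$trees[[t]], X)
  out
}

predict_engine <- function(forest, X, eval_times, use = NULL) {
  eval_times <- as.numeric(eval_times)
  terms_new <- terminal_ids_matrix(forest, X)
  if (forest$rule == "cif") {
    W <- cif_weight_matrix_cpp(forest$train_terms, terms_new,
                               forest$inbag, use)
    surv <- weighted_km_cpp(W, forest$time, forest$event, eval_times)
    empty <- rowSums(W) <= 0
    if (any(empty)) {
      surv[empty, ] <- NA_real_
      warning(sum(empty), " subject(s) have no contributing trees; predictions set to NA")
    }
  } else {
    chf <- lapply(forest$trees, function(tr)
      terminal_chf_cpp(tr$members, forest$time, forest$event, eval_times))
    H <- ensemble_chf_cpp(terms_new, chf, use)
    if (anyNA(H[, 1]))
      warning(sum(is.na(H[, 1])), " subject(s) have no contributing trees; predictions set to NA")
    surv <- exp(-H)
  }
  dimnames(surv) <- NULL
  attr(surv, "times") <- eval_times
  surv
}

#' Ensemble survival predictions
#'
#' Drops each new subject down every tree and aggregates terminal-node
#' estimates: averaged Nelson-Aalen cumulative hazards (converted to
#' survival) for random survival forests, the terminal-size-normalized
#' weighted Kaplan-Meier over the training set for conditional inference
#' forests. Predicted curves are proper: within \[0, 1\], non-increasing,
#' starting at 1.
#'
#' @param forest A fitted `surv_forest`.
#' @param newdata A `surv_data` or covariate data.frame; default the training
#'   data.
#' @param eval_times Evaluation time grid (increasing).
#' @return Matrix of survival probabilities, one row per subject, one column
#'   per evaluation time, with the grid in `attr(, "times")`.
#' @export
predict_survival <- function(forest, newdata = NULL, eval_times) {
  X <- encode_with(new_cov_frame(forest, newdata), forest$enc)
  predict_engine(forest, X, eval_times)
}

#' @export
predict.surv_forest <- function(object, newdata = NULL, eval_times, ...) {
  predict_survival(object, newdata, eval_times)
}

#' Out-of-bag ensemble survival predictions
#'
#' As [predict_survival()] on the training subjects, but each subject's
#' prediction uses only the trees in whose bootstrap/subsample it did not
#' appear. Subjects that are in-bag in every tree get `NA` predictions with
#' a warning.
#'
#' @param forest A fitted `surv_forest`.
#' @param eval_times Evaluation time grid.
#' @param covariates Optional replacement covariate frame for the training
#'   subjects (used by permutation importance).
#' @return Matrix of survival probabilities (training subjects by times).
#' @export
oob_predict <- function(forest, eval_times, covariates = NULL) {
  cov <- if (is.null(covariates)) forest$covariates else covariates
  X <- encode_with(cov, forest$enc)
  use <- matrix(as.integer(forest$oob), nrow(forest$oob), ncol(forest$oob))
  predict_engine(forest, X, eval_times, use = use)
}

#' Permutation variable importance
#'
#' Importance of a covariate is the increase in out-of-bag integrated Brier
#' score after randomly permuting that covariate's column (averaged over
#' `n_perm` permutations). Larger values mean the forest's predictions rely
#' more on the covariate; a covariate never used in any split scores ~0.
#'
#' @param forest A fitted `surv_forest`.
#' @param eval_times Evaluation grid; default the forest's training event
#'   times (thinned, truncated where the censoring survival is positive).
#' @param n_perm Permutations per covariate (default 1).
#' @param seed Optional seed for the permutations.
#' @return data.frame with columns `variable`, `importance`, `rank`.
#' @export
permutation_vimp <- function(forest, eval_times = NULL, n_perm = 1L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- censoring_km(forest$time, forest$event)
  if (is.null(eval_times))
    eval_times <- eval_time_grid(forest$time, forest$event, G)
  base <- oob_predict(forest, eval_times)
  ibs0 <- integrated_brier(
    brier_curve(base, forest$time, forest$event, eval_times, G), eval_times)
  n <- length(forest$time)
  imp <- vapply(names(forest$covariates), function(v) {
    mean(vapply(seq_len(n_perm), function(k) {
      cov <- forest$covariates
      cov[[v]] <- cov[[v]][sample.int(n)]
      pred <- oob_predict(forest, eval_times, covariates = cov)
      integrated_brier(
        brier_curve(pred, forest$time, forest$event, eval_times, G),
        eval_times) - ibs0
    }, 0))
  }, 0)
  out <- data.frame(variable = names(forest$covariates), importance = imp,
                    row.names = NULL)
  out$rank <- rank(-out$importance, ties.method = "first")
  out
}
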