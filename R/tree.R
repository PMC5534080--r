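# Covariate encoding shared by trees, forests and prediction.
#
# Factors/characters become integer level codes 1..L and are split by level
# subsets (unordered); numeric columns (including 0/1 binaries) are split by
# thresholds. Unordered covariates are limited to `max_levels` levels because
# subset search is exhaustive over the 2^(L-1)-1 proper subsets.
encode_covariates <- function(cov, max_levels = 8L) {
  p <- ncol(cov)
  X <- matrix(0, nrow(cov), p)
  unordered <- logical(p)
  levels_map <- vector("list", p)
  for (j in seq_len(p)) {
    col <- cov[[j]]
    if (is.factor(col) || is.character(col)) {
      f <- if (is.factor(col)) droplevels(col) else factor(col)
      if (nlevels(f) > max_levels)
        stop("covariate '", names(cov)[j], "' has ", nlevels(f),
             " levels; exhaustive subset search supports at most ",
             max_levels)
      X[, j] <- as.integer(f)
      unordered[j] <- TRUE
      levels_map[[j]] <- levels(f)
    } else {
      X[, j] <- as.numeric(col)
    }
  }
  list(X = X, unordered = unordered, levels = levels_map, names = names(cov))
}

# Encode new data with a training encoding; unseen factor levels become NA
# (routed to the larger child during traversal).
encode_with <- function(cov, enc) {
  if (!all(enc$names %in% names(cov)))
    stop("newdata lacks covariate(s): ",
         paste(setdiff(enc$names, names(cov)), collapse = ", "))
  p <- length(enc$names)
  X <- matrix(0, nrow(cov), p)
  unseen <- 0L
  for (j in seq_len(p)) {
    col <- cov[[enc$names[j]]]
    if (enc$unordered[j]) {
      code <- match(as.character(col), enc$levels[[j]])
      unseen <- unseen + sum(is.na(code) & !is.na(col))
      X[, j] <- code
    } else {
      X[, j] <- as.numeric(col)
    }
  }
  if (unseen > 0L)
    warning(unseen, " covariate value(s) unseen in training; routed to the larger child")
  X
}

forest_rule_code <- function(rule) {
  switch(rule, logrank = 0L, logrank_score = 1L, cif = 2L,
         stop("unknown rule '", rule, "'"))
}

#' Grow a single survival tree
#'
#' Recursive binary partitioning of right-censored data under the log-rank or
#' the log-rank-score split rule. At each node `mtry` candidate covariates are
#' drawn without replacement; the rule's statistic is maximized over all
#' admissible splits (thresholds for numeric covariates, exhaustive proper
#' level subsets for factors). A split is admissible when both children have
#' at least `min_node_size` subjects and `min_events` events; ties between
#' equal-statistic splits go to the lowest covariate index, then the smallest
#' split set in canonical order. Terminal nodes carry the member index list
#' and a Kaplan-Meier curve of their members.
#'
#' @param data A `surv_data` object with at least one event.
#' @param rule `"logrank"` or `"logrank_score"`.
#' @param mtry Candidate covariates per node; default `ceiling(sqrt(p))`.
#' @param min_node_size Minimum subjects per child (default 15).
#' @param min_events Minimum events per child (default 3).
#' @param seed Optional integer seed for the candidate draws.
#' @return An object of class `surv_tree`.
#' @export
grow_tree <- function(data, rule = c("logrank", "logrank_score"), mtry = NULL,
                      min_node_size = 15L, min_events = 3L, seed = NULL) {
  rule <- match.arg(rule)
  grow_tree_impl(data, rule, mtry, min_node_size, min_events, seed,
                 alpha = 1, small_n = 30L, n_perm = 9999L)
}

grow_tree_impl <- function(data, rule, mtry, min_node_size, min_events, seed,
                           alpha, small_n, n_perm) {
  n <- n_subjects(data)
  p <- ncol(data$covariates)
  if (is.null(mtry)) mtry <- if (rule == "cif") p else ceiling(sqrt(p))
  if (sum(data$event) == 0)
    warning("all subjects censored: returning a root-only tree with a flat survival curve")
  enc <- encode_covariates(data$covariates)
  if (!is.null(seed)) set.seed(seed)
  nodes <- grow_tree_cpp(data$time, data$event, enc$X, enc$unordered,
                         seq_len(n), forest_rule_code(rule), as.integer(mtry),
                         as.integer(min_node_size), as.integer(min_events),
                         alpha, as.integer(small_n), as.integer(n_perm))
  structure(list(nodes = nodes, enc = enc, time = data$time,
                 event = data$event,
                 grow_params = list(rule = rule, mtry = mtry,
                                    min_node_size = min_node_size,
                                    min_events = min_events, alpha = alpha,
                                    seed = seed)),
            class = "surv_tree")
}

#' Grow a single conditional inference survival tree
#'
#' At each node the association of every candidate covariate with the node's
#' log-rank scores is tested in the permutation framework (see
#' [linear_rank_test()]); Bonferroni-adjusted minimum-p selection picks the
#' split variable, and the node becomes terminal when no adjusted p-value is
#' at most `alpha`. The split point on the selected variable then maximizes
#' the two-sample linear rank (log-rank-score) statistic.
#'
#' @inheritParams grow_tree
#' @param alpha Per-node stopping level (default 0.05).
#' @param mtry Candidate covariates per node; default all.
#' @param small_n Node size below which Monte-Carlo permutation p-values are
#'   used (default 30).
#' @param n_perm Monte-Carlo permutations (default 9999).
#' @return An object of class `surv_tree`.
#' @export
grow_ctree <- function(data, alpha = 0.05, mtry = NULL, min_node_size = 15L,
                       min_events = 3L, seed = NULL, small_n = 30L,
                       n_perm = 9999L) {
  grow_tree_impl(data, "cif", mtry, min_node_size, min_events, seed,
                 alpha = alpha, small_n = small_n, n_perm = n_perm)
}

#' Terminal-node assignment of a survival tree
#' @param tree A `surv_tree`.
#' @param newdata A `surv_data` or covariate data.frame.
#' @return Integer terminal ids (numbered in tree node order).
#' @export
predict_node <- function(tree, newdata) {
  cov <- if (inherits(newdata, "surv_data")) newdata$covariates else newdata
  predict_terminal_cpp(tree$nodes, encode_with(cov, tree$enc))
}

#' Member index lists of a tree's terminal nodes
#' @param tree A `surv_tree`.
#' @return List of integer vectors of training row indices (with bootstrap
#'   multiplicity, if any), one per terminal node.
#' @export
terminal_members <- function(tree) tree$nodes$members

#' Kaplan-Meier curves of a tree's terminal nodes
#' @param tree A `surv_tree`.
#' @return List of [surv_curve()] objects, one per terminal node.
#' @export
terminal_curves <- function(tree) {
  lapply(tree$nodes$members, function(m)
    kaplan_meier(tree$time[m], tree$event[m]))
}

#' Best single split of a node
#'
#' Exhaustive search for the split maximizing the chosen rule's statistic over
#' the candidate covariates, honoring the child-size and child-event
#' admissibility constraints. Returns `NULL` when no admissible split exists.
#'
#' @param data A `surv_data` (the node's subjects).
#' @param candidate_vars Covariate names to search (default all).
#' @param rule `"logrank"` or `"logrank_score"`.
#' @param min_node_size,min_events Admissibility constraints per child.
#' @return `NULL`, or a list with `variable`, `statistic`, `left_size`, and
#'   either `threshold` (numeric covariate) or `levels_left` (factor).
#' @export
best_split <- function(data, candidate_vars = names(data$covariates),
                       rule = c("logrank", "logrank_score"),
                       min_node_size = 1L, min_events = 1L) {
  rule <- match.arg(rule)
  enc <- encode_covariates(data$covariates)
  vidx <- match(candidate_vars, enc$names)
  if (anyNA(vidx)) stop("unknown covariate(s): ",
                        paste(candidate_vars[is.na(vidx)], collapse = ", "))
  res <- node_best_split_cpp(data$time, data$event, enc$X, enc$unordered,
                             as.integer(vidx), forest_rule_code(rule),
                             as.integer(min_node_size), as.integer(min_events))
  if (!res$found) return(NULL)
  out <- list(variable = enc$names[res$var], statistic = res$stat,
              left_size = res$left_n)
  if (res$ordered) {
    out$threshold <- res$threshold
  } else {
    lv <- enc$levels[[res$var]]
    bits <- which(bitwAnd(as.integer(res$left_mask),
                          bitwShiftL(1L, seq_along(lv) - 1L)) > 0L)
    out$levels_left <- lv[bits]
  }
  out
}

#' @export
print.surv_tree <- function(x, ...) {
  nt <- sum(x$nodes$split_var == 0)
  cat(sprintf("Survival tree (%s rule): %d nodes, %d terminal\n",
              x$grow_params$rule, length(x$nodes$split_var), nt))
  invisible(x)
}

#' Serialize a survival tree to a line-oriented text format
#'
#' One line per node: internal nodes show the split, terminal nodes the
#' member count and Kaplan-Meier knots, suitable for inspection and fixtures.
#'
#' @param tree A `surv_tree`.
#' @return Character vector, one line per node.
#' @export
format_tree <- function(tree) {
  nd <- tree$nodes
  km <- terminal_curves(tree)
  vapply(seq_along(nd$split_var), function(i) {
    if (nd$split_var[i] != 0L) {
      v <- nd$split_var[i]
      desc <- if (!is.na(nd$split_value[i])) {
        sprintf("%s <= %.6g", tree$enc$names[v], nd$split_value[i])
      } else {
        lv <- tree$enc$levels[[v]]
        bits <- which(bitwAnd(as.integer(nd$left_mask[i]),
                              bitwShiftL(1L, seq_along(lv) - 1L)) > 0L)
        sprintf("%s in {%s}", tree$enc$names[v], paste(lv[bits], collapse = ","))
      }
      sprintf("node %d: split %s -> (%d, %d) stat %.4f n=%d", i, desc,
              nd$child_left[i], nd$child_right[i], nd$split_stat[i], nd$n_node[i])
    } else {
      cv <- km[[nd$terminal_id[i]]]
      sprintf("node %d: terminal #%d n=%d km=[%s]", i, nd$terminal_id[i],
              nd$n_node[i],
              paste(sprintf("%.4g:%.4g", cv$times, cv$surv), collapse = " "))
    }
  }, "")
}
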