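config_defaults <- function() {
  list(designs = "all", models = c("rsf1", "rsf2", "cif"), n_trees = 100L,
       n_reps = 10L, B = 5L, base_seed = 1L, output_dir = "survforests-run",
       alpha = NA_real_, mtry = NA_integer_, min_node_size = NA_integer_,
       min_events = NA_integer_, subsample_fraction = 0.632)
}

#' Build a validated benchmark run configuration
#'
#' @param ... Configuration fields overriding the defaults: `designs`
#'   (design ids or `"all"`), `models` (subset of rsf1/rsf2/cif), `n_trees`,
#'   `n_reps`, `B`, `base_seed`, `output_dir`, and per-model hyperparameters
#'   `alpha`, `mtry`, `min_node_size`, `min_events`, `subsample_fraction`.
#' @return A `run_config` list with all defaults resolved.
#' @export
run_config <- function(...) {
  user <- list(...)
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (length(cfg$models) == 0L) stop("models must not be empty")
  bad <- setdiff(cfg$models, c("rsf1", "rsf2", "cif"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (identical(cfg$designs, "all")) cfg$designs <- names(builtin_designs())
  missing_d <- setdiff(cfg$designs, names(builtin_designs()))
  if (length(missing_d))
    stop("unknown design id(s): ", paste(missing_d, collapse = ", "))
  for (f in c("n_trees", "n_reps", "B"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      stop("field '", f, "' must be a positive integer")
  structure(cfg, class = "run_config")
}

#' Load a benchmark configuration from a YAML file
#'
#' Unknown keys are a hard error (no silently ignored typos); missing keys
#' take the documented defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a resolved configuration back to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Execute a benchmark run
#'
#' Runs [benchmark_repetitions()] for the configured designs and models and
#' writes `results.csv`, the resolved configuration echo and a software
#' manifest into the output directory. Rerunning with the same `base_seed`
#' reproduces the results table exactly.
#'
#' @param config A `run_config` (see [run_config()] / [load_config()]).
#' @return The results data.frame, invisibly.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  opt <- function(x) if (length(x) == 1 && is.na(x)) NULL else x
  models <- standard_models(n_trees = config$n_trees,
                            alpha = opt(config$alpha),
                            mtry = opt(config$mtry),
                            min_node_size = opt(config$min_node_size),
                            min_events = opt(config$min_events),
                            subsample_fraction = config$subsample_fraction)
  models <- models[config$models]
  res <- benchmark_repetitions(as.list(config$designs), models,
                               n_reps = config$n_reps, B = config$B,
                               seed = config$base_seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res, file.path(config$output_dir, "results.csv"),
                   row.names = FALSE)
  write_config(config, file.path(config$output_dir, "config.yaml"))
  writeLines(c(paste("survforests", as.character(utils::packageVersion("survforests"))),
               R.version.string,
               paste("run at", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(config$output_dir, "manifest.txt"))
  invisible(res)
}

#' Box plot of benchmark prediction errors
#'
#' Draws per-design box plots of the .632+ integrated Brier scores by model,
#' the standard visual comparison of the three forests.
#'
#' @param results data.frame from [benchmark_repetitions()].
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the results split used for plotting.
#' @export
plot_benchmark <- function(results, ...) {
  sp <- split(results$ibs, interaction(results$model, results$design))
  graphics::boxplot(sp, las = 2, ylab = "Integrated Brier score (.632+)", ...)
  graphics::abline(h = 0.25, lty = 2)
  invisible(sp)
}
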