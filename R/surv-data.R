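#' Construct a right-censored survival dataset
#'
#' Bundles observed follow-up times, event indicators and a covariate frame
#' into the container consumed by all model-fitting and evaluation functions.
#' Binary covariates are stored as 0/1 numerics, polytomous (multi-level
#' categorical) covariates as factors; any other numeric column is treated as
#' an ordered covariate when fitting.
#'
#' @param time Non-negative observed times (event or censoring).
#' @param event Event indicators, 1 = event observed, 0 = right censored.
#' @param covariates A data.frame of covariates (at least one column).
#' @param latent_event,latent_censor Optional latent event/censoring times
#'   retained by the simulation engine for diagnostics; when both are present
#'   the observed data must satisfy `time == pmin(latent_event, latent_censor)`
#'   and `event == (latent_event <= latent_censor)`.
#' @param design_id Optional label of the simulation design that produced the
#'   data.
#' @return An object of class `surv_data`: a list with elements `time`,
#'   `event`, `covariates` and the optional latent vectors.
#' @export
survival_dataset <- function(time, event, covariates,
                             latent_event = NULL, latent_censor = NULL,
                             design_id = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  n <- length(time)
  if (length(event) != n || nrow(covariates) != n)
    stop("time, event and covariates must have the same number of rows")
  if (n < 1L) stop("empty dataset")
  if (ncol(covariates) < 1L) stop("at least one covariate column is required")
  if (anyNA(time) || any(time < 0)) stop("times must be non-negative and non-missing")
  if (!all(event %in% c(0L, 1L))) stop("event indicators must be 0 or 1")
  if (!is.null(latent_event) && !is.null(latent_censor)) {
    stopifnot(length(latent_event) == n, length(latent_censor) == n)
    if (max(abs(time - pmin(latent_event, latent_censor))) > 1e-8)
      stop("observed time must equal min(latent event, latent censoring)")
    if (!all(event == as.integer(latent_event <= latent_censor)))
      stop("event indicator inconsistent with latent times")
  }
  structure(list(time = time, event = event, covariates = covariates,
                 latent_event = latent_event, latent_censor = latent_censor,
                 design_id = design_id),
            class = "surv_data")
}

#' @export
print.surv_data <- function(x, ...) {
  cat(sprintf("Right-censored survival dataset: %d subjects, %d covariates\n",
              length(x$time), ncol(x$covariates)))
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(x$event),
              100 * mean(x$event == 0)))
  if (!is.null(x$design_id)) cat("  design:", x$design_id, "\n")
  invisible(x)
}

#' @export
as.data.frame.surv_data <- function(x, ...) {
  cbind(data.frame(time = x$time, event = x$event), x$covariates)
}

#' Number of subjects in a survival dataset
#' @param data A `surv_data` object.
#' @return Integer count of subjects.
#' @export
n_subjects <- function(data) length(data$time)

#' Subset a survival dataset by row index
#'
#' Rows may repeat (e.g. bootstrap resampling).
#' @param data A `surv_data` object.
#' @param idx Integer row indices.
#' @return A `surv_data` with the selected rows.
#' @export
subset_surv <- function(data, idx) {
  survival_dataset(data$time[idx], data$event[idx],
                   data$covariates[idx, , drop = FALSE],
                   latent_event = if (!is.null(data$latent_event)) data$latent_event[idx],
                   latent_censor = if (!is.null(data$latent_censor)) data$latent_censor[idx],
                   design_id = data$design_id)
}

#' Write a survival dataset to CSV
#'
#' Header row `time,event,<covariates...>`; factor levels are written as their
#' string labels. The output is plain text and byte-stable for a fixed dataset.
#'
#' @param data A `surv_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(data, path) {
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival dataset from CSV
#'
#' Expects the layout written by [write_survival_csv()]: columns `time`,
#' `event`, then covariates. Character columns become factors (polytomous
#' covariates); numeric columns with values in \{0,1\} are kept as binary.
#'
#' @param path CSV file path.
#' @return A `surv_data` object.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = TRUE)
  if (!all(c("time", "event") %in% names(df)))
    stop("CSV must contain 'time' and 'event' columns")
  cov <- df[, setdiff(names(df), c("time", "event")), drop = FALSE]
  survival_dataset(df$time, df$event, cov)
}
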