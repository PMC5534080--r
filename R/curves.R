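#' Right-continuous survival step function
#'
#' A survival curve is represented by its knot times (increasing) and the
#' value of the curve just after each knot; the value before the first knot
#' is 1. Used both for event survival estimates S(t) and for censoring
#' survival estimates G(t).
#'
#' @param times Increasing knot times.
#' @param surv Values in \[0, 1\], non-increasing, one per knot.
#' @return An object of class `surv_curve`.
#' @export
surv_curve <- function(times, surv) {
  if (length(times) != length(surv)) stop("times and surv must match")
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("knot times must be strictly increasing")
  if (length(surv) && (any(surv < -1e-12) || any(surv > 1 + 1e-12)))
    stop("survival values must lie in [0, 1]")
  if (length(surv) > 1 && any(diff(surv) > 1e-12))
    stop("survival values must be non-increasing")
  structure(list(times = as.numeric(times), surv = pmin(pmax(surv, 0), 1)),
            class = "surv_curve")
}

#' Evaluate a survival step function
#'
#' Right-continuous step interpolation; values before the first knot are 1.
#'
#' @param curve A [surv_curve()].
#' @param t Evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
eval_curve <- function(curve, t) {
  c(1, curve$surv)[findInterval(t, curve$times) + 1L]
}

#' @export
print.surv_curve <- function(x, ...) {
  cat(sprintf("Survival step function with %d knots", length(x$times)))
  if (length(x$times))
    cat(sprintf(" on [%.4g, %.4g], final value %.4g", min(x$times),
                max(x$times), x$surv[length(x$surv)]))
  cat("\n")
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' Standard product-limit estimate of the event survival function S(t):
#' at each distinct event time, S is multiplied by (1 - d/n) with d the
#' events and n the subjects at risk (subjects censored at the same time
#' still count as at risk: censorings are taken to occur after events).
#'
#' @param time Observed times.
#' @param event Event indicators (1 = event).
#' @return A [surv_curve()] with knots at the distinct event times.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) < 1L) stop("empty input")
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) return(surv_curve(numeric(0), numeric(0)))
  atrisk <- vapply(dt, function(s) sum(time >= s), 0)
  d <- vapply(dt, function(s) sum(time == s & event == 1), 0)
  surv_curve(dt, cumprod(1 - d / atrisk))
}

#' Kaplan-Meier estimator of the censoring survival function
#'
#' The product-limit estimator applied with the event indicator reversed:
#' censorings act as events. Ties between events and censorings at the same
#' time are resolved by letting censorings occur just after events, so the
#' at-risk set for a censoring excludes subjects with an event at that time
#' (the standard IPCW convention).
#'
#' @param time Observed times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A [surv_curve()] for G(t) with knots at distinct censoring times.
#' @export
censoring_km <- function(time, event) {
  if (length(time) < 1L) stop("empty input")
  dt <- sort(unique(time[event == 0]))
  if (!length(dt)) return(surv_curve(numeric(0), numeric(0)))
  atrisk <- vapply(dt, function(s) sum(time >= s) - sum(time == s & event == 1), 0)
  cns <- vapply(dt, function(s) sum(time == s & event == 0), 0)
  fac <- ifelse(atrisk > 0, 1 - cns / atrisk, 0)
  surv_curve(dt, cumprod(fac))
}

# Nelson-Aalen cumulative hazard (reference implementation; the forest
# ensemble uses the C++ equivalent per terminal node).
nelson_aalen <- function(time, event, eval_times) {
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) return(rep(0, length(eval_times)))
  atrisk <- vapply(dt, function(s) sum(time >= s), 0)
  d <- vapply(dt, function(s) sum(time == s & event == 1), 0)
  H <- cumsum(d / atrisk)
  c(0, H)[findInterval(eval_times, dt) + 1L]
}
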