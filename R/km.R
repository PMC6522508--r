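#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator
#' \deqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' with Greenwood standard errors. At tied times, events are processed before
#' censorings (the standard convention), i.e. observations censored at an
#' event time are still in the risk set at that time.
#'
#' @param time_days Non-negative follow-up times.
#' @param event Logical event indicators (TRUE = death/deterioration).
#' @return An object of class \code{km_curve}: a list with \code{time}
#'   (distinct event times, ascending), \code{n_risk}, \code{n_event},
#'   \code{surv}, \code{se} (Greenwood), plus totals \code{n} and
#'   \code{n_events}.
#' @seealso \code{\link{km_survival_at}}
#' @export
km_fit <- function(time_days, event) {
  if (length(time_days) < 1) stop("empty input", call. = FALSE)
  if (length(event) != length(time_days))
    stop("time_days and event must have equal length", call. = FALSE)
  if (any(is.na(time_days)) || any(time_days < 0))
    stop("time_days must be non-negative", call. = FALSE)
  event <- as.logical(event)
  ut <- sort(unique(time_days[event]))
  st <- sort(time_days)
  # risk set: all with time >= t (ties: censorings at t still at risk)
  n_risk <- length(st) - findInterval(ut, st, left.open = TRUE)
  d <- tabulate(match(time_days[event], ut), length(ut))
  surv <- cumprod(1 - d / n_risk)
  gw <- surv^2 * cumsum(d / (n_risk * pmax(n_risk - d, 1)))
  se <- ifelse(n_risk == d, NA_real_, sqrt(gw))  # undefined after S hits 0
  structure(list(time = ut, n_risk = n_risk, n_event = d, surv = surv,
                 se = se, n = length(time_days), n_events = sum(event)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation; times before the first event
#' give 1, times beyond the last event give the final survival value.
#'
#' @param curve A \code{\link{km_fit}} object.
#' @param t_days Evaluation times (>= 0). Vectorized.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t_days) {
  if (any(t_days < 0)) stop("t_days must be >= 0", call. = FALSE)
  c(1, curve$surv)[findInterval(t_days, curve$time) + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d\n", x$n, x$n_events))
  if (length(x$time)) {
    show <- utils::head(data.frame(time = x$time, n_risk = x$n_risk,
                                   n_event = x$n_event,
                                   surv = round(x$surv, 4),
                                   se = round(x$se, 4)), 10)
    print(show, row.names = FALSE)
    if (length(x$time) > 10) cat("  ...", length(x$time), "event times\n")
  } else cat("  no events: S(t) = 1\n")
  invisible(x)
}

#' Export a Kaplan-Meier curve as a data.frame
#'
#' @param x A \code{km_curve}.
#' @param ... Unused.
#' @return data.frame with time, n_risk, n_event, surv, se.
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             surv = x$surv, se = x$se)
}
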