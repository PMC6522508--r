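#' k-group log-rank test
#'
#' Standard log-rank chi-square over k groups with the hypergeometric
#' (tie-corrected) variance: at each distinct pooled event time \eqn{t_j}
#' with \eqn{d_j} events among \eqn{n_j} at risk, the group event counts are
#' compared with their conditional expectations \eqn{n_{gj} d_j / n_j}, and
#' the quadratic form of the summed differences in the inverse of the summed
#' hypergeometric covariance gives a chi-square statistic on k - 1 degrees of
#' freedom. No stratification.
#'
#' @param time_days Pooled follow-up times.
#' @param event Logical event indicators.
#' @param group Group labels (factor, character, or logical); at least two
#'   non-empty groups.
#' @return An object of class \code{logrank_test}: list with
#'   \code{statistic}, \code{df}, \code{p_value}, \code{observed},
#'   \code{expected}, \code{n} (per group).
#' @export
logrank_test <- function(time_days, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (length(time_days) != length(event) || length(time_days) != length(group))
    stop("time_days, event and group must have equal length", call. = FALSE)
  event <- as.logical(event)
  ut <- sort(unique(time_days[event]))
  if (!length(ut))
    stop("degenerate input: no events in pooled data", call. = FALSE)
  J <- length(ut)
  st <- sort(time_days)
  n_j <- length(st) - findInterval(ut, st, left.open = TRUE)
  d_j <- tabulate(match(time_days[event], ut), J)

  n_gj <- matrix(0, k, J)
  d_gj <- matrix(0, k, J)
  for (g in seq_len(k)) {
    tg <- sort(time_days[group == levels(group)[g]])
    n_gj[g, ] <- length(tg) - findInterval(ut, tg, left.open = TRUE)
    d_gj[g, ] <- tabulate(match(time_days[event & group == levels(group)[g]],
                                ut), J)
  }
  O <- rowSums(d_gj)
  E <- rowSums(n_gj * rep(d_j / n_j, each = k))
  # hypergeometric covariance, summed over event times
  w <- d_j * (n_j - d_j) / pmax(n_j - 1, 1)
  w[n_j <= 1] <- 0
  P <- n_gj / rep(n_j, each = k)
  V <- diag(drop(P %*% w), k) - P %*% (w * t(P))
  U <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(crossprod(U, solve(Vk, U))),
                   error = function(e)
                     stop("degenerate input: singular log-rank variance",
                          call. = FALSE))
  structure(list(statistic = stat, df = k - 1L,
                 p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group)),
                 n = stats::setNames(as.integer(table(group)),
                                     levels(group))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(n = x$n, observed = x$observed,
                   expected = round(x$expected, 2)))
  invisible(x)
}

#' Permutation log-rank p-value
#'
#' Monte-Carlo reference distribution for the log-rank statistic obtained by
#' permuting group labels; serves as a small-sample oracle for the asymptotic
#' chi-square p-value and as the optional stopping test of the survival tree.
#' Returns \eqn{p = (1 + \#\{T^{perm} \ge T^{obs}\}) / (n_{perm} + 1)}.
#'
#' @inheritParams logrank_test
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer RNG seed (deterministic given seed).
#' @return List with \code{p_value}, \code{statistic} (observed), and
#'   \code{n_perm}.
#' @export
permutation_logrank <- function(time_days, event, group, n_perm = 999L,
                                seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  obs <- logrank_test(time_days, event, group)$statistic
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    stat_b <- logrank_test(time_days, event, sample(group))$statistic
    if (stat_b >= obs - 1e-12) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), statistic = obs,
       n_perm = as.integer(n_perm))
}
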