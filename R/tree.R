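#' Survival-tree configuration
#'
#' Controls the recursive partitioning of waitlist survival over integer MELD
#' thresholds. Split selection uses the log-rank-scores linear statistic in
#' its conditional-inference form (see \code{\link{candidate_splits}}); a
#' node is split at the threshold with the maximal statistic, and the split
#' is accepted only when its p-value (asymptotic chi-square on 1 df, or a
#' permutation p with \code{n_perm} draws), Bonferroni-corrected for the
#' number of candidate thresholds at the node, falls below \code{alpha}.
#' Under a homogeneous-hazard null this stopping rule splits with
#' probability at most \code{alpha}, which is the overfitting control the
#' partitioning framework is used for.
#'
#' @param alpha Stopping significance level in (0, 1).
#' @param min_node_size Minimum samples in each child (default 50).
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param n_perm Permutations for the split test; 0 = asymptotic p-value.
#' @param horizon_days Horizon for node survival summaries (90 or 14).
#' @param multiplicity Bonferroni-correct over candidate thresholds.
#' @param seed Seed for the permutation test.
#' @return Object of class \code{tree_config}.
#' @export
tree_config <- function(alpha = 0.05, min_node_size = 50L, max_depth = 4L,
                        n_perm = 0L, horizon_days = 90, multiplicity = TRUE,
                        seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (min_node_size < 1) stop("min_node_size must be >= 1", call. = FALSE)
  if (n_perm < 0) stop("n_perm must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth), n_perm = as.integer(n_perm),
                 horizon_days = horizon_days, multiplicity = multiplicity,
                 seed = as.integer(seed)),
            class = "tree_config")
}

# log-rank scores (martingale residuals at the observed time):
# a_i = delta_i - NelsonAalen(t_i), with events before censorings at ties.
# They sum to zero exactly within a node.
logrank_scores <- function(time_days, event) {
  ut <- sort(unique(time_days[event]))
  st <- sort(time_days)
  n_risk <- length(st) - findInterval(ut, st, left.open = TRUE)
  d <- tabulate(match(time_days[event], ut), length(ut))
  cumhaz <- c(0, cumsum(d / n_risk))
  event - cumhaz[findInterval(time_days, ut) + 1L]
}

#' Score all candidate MELD split thresholds at a node
#'
#' Every integer threshold c for which both children (MELD <= c vs > c) hold
#' at least \code{min_node_size} samples is scored by the log-rank-scores
#' two-sample statistic in its permutation (conditional-inference) form: the
#' node's log-rank scores \eqn{a_i} are computed once, and each threshold is
#' scored by \eqn{\chi^2_c = T_c^2 / V_c} with \eqn{T_c = \sum_{MELD_i \le c}
#' a_i} and the exact permutation variance \eqn{V_c = n_L n_R /(n(n-1))
#' \sum a_i^2}, referred to chi-square on 1 df. P-values are
#' Bonferroni-adjusted for the number of candidates when \code{multiplicity}
#' is on.
#'
#' @param meld Integer MELD scores of the node's samples.
#' @param time_days,event Survival outcome of the node's samples.
#' @param config A \code{\link{tree_config}}.
#' @return data.frame(threshold, n_left, statistic, p_value, p_adj), possibly
#'   with zero rows when no threshold is feasible.
#' @export
candidate_splits <- function(meld, time_days, event, config = tree_config()) {
  n <- length(meld)
  vals <- sort(unique(meld))
  n_left <- cumsum(tabulate(match(meld, vals), length(vals)))
  ok <- n_left >= config$min_node_size & (n - n_left) >= config$min_node_size
  thresholds <- vals[ok]
  empty <- data.frame(threshold = integer(0), n_left = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0))
  if (!length(thresholds)) return(empty)
  if (!any(event)) return(empty)  # no events: no split information
  a <- logrank_scores(time_days, as.logical(event))
  ssq <- sum(a^2)
  if (ssq <= 0) return(empty)
  # cumulative score sums over ascending MELD values
  Tc <- cumsum(vapply(vals, function(v) sum(a[meld == v]), 0))[ok]
  nl <- n_left[ok]
  V <- nl * (n - nl) / (n * (n - 1)) * ssq
  stat <- Tc^2 / V
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  nc <- length(thresholds)
  data.frame(threshold = thresholds, n_left = nl, statistic = stat,
             p_value = p,
             p_adj = if (config$multiplicity) pmin(1, p * nc) else p)
}

# permutation p-value of the score statistic for one threshold
perm_split_p <- function(meld, time_days, event, threshold, n_perm, seed) {
  a <- logrank_scores(time_days, as.logical(event))
  n <- length(a)
  nl <- sum(meld <= threshold)
  V <- nl * (n - nl) / (n * (n - 1)) * sum(a^2)
  obs <- sum(a[meld <= threshold])^2 / V
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    stat_b <- sum(a[sample.int(n, nl)])^2 / V
    if (stat_b >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Fit a survival tree over the MELD covariate
#'
#' Recursive binary partitioning: at each node the exhaustive-search argmax
#' threshold is selected (ties broken to the smallest threshold); the node
#' becomes a leaf when the adjusted p-value of the best split is not below
#' \code{alpha}, the depth limit is reached, or no feasible threshold
#' remains. Splitting uses full follow-up; \code{horizon_days} only enters
#' the node survival summaries.
#'
#' @inheritParams candidate_splits
#' @return Nested node structure of class \code{meld_tree}. Each node carries
#'   \code{n}, \code{meld_lo}/\code{meld_hi}, \code{n_events},
#'   \code{surv_horizon} (KM at the configured horizon), and for internal
#'   nodes \code{threshold}, \code{statistic}, \code{p_value}, \code{p_adj},
#'   \code{n_candidates}, \code{left}, \code{right}.
#' @export
fit_tree <- function(meld, time_days, event, config = tree_config()) {
  if (!length(meld)) stop("empty input", call. = FALSE)
  if (length(meld) != length(time_days) || length(meld) != length(event))
    stop("meld, time_days and event must have equal length", call. = FALSE)

  build <- function(idx, depth, lo, hi) {
    m <- meld[idx]; tt <- time_days[idx]; ev <- event[idx]
    km <- km_fit(tt, ev)
    node <- list(n = length(idx), meld_lo = lo, meld_hi = hi,
                 n_events = sum(ev), depth = depth,
                 surv_horizon = km_survival_at(km, config$horizon_days),
                 threshold = NULL)
    if (depth >= config$max_depth || length(idx) < 2 * config$min_node_size)
      return(node)
    cs <- candidate_splits(m, tt, ev, config)
    if (!nrow(cs)) return(node)
    best <- which.max(cs$statistic)  # first max = smallest threshold on ties
    cth <- cs$threshold[best]
    p <- if (config$n_perm > 0) {
      perm_split_p(m, tt, ev, cth, config$n_perm,
                   seed = config$seed + 131L * depth + cth)
    } else cs$p_value[best]
    p_adj <- if (config$multiplicity) min(1, p * nrow(cs)) else p
    node$statistic <- cs$statistic[best]
    node$p_value <- p
    node$p_adj <- p_adj
    node$n_candidates <- nrow(cs)
    if (p_adj >= config$alpha) return(node)
    node$threshold <- as.integer(cth)
    node$left <- build(idx[m <= cth], depth + 1L, lo, as.integer(cth))
    node$right <- build(idx[m > cth], depth + 1L, as.integer(cth) + 1L, hi)
    node
  }
  tree <- build(seq_along(meld), 0L, as.integer(min(meld)),
                as.integer(max(meld)))
  tree$config <- config
  class(tree) <- "meld_tree"
  tree
}

#' Extract the leaf strata of a fitted survival tree
#'
#' @param tree A \code{\link{fit_tree}} result.
#' @return data.frame of leaf MELD ranges in ascending order with sample
#'   counts, event counts and survival at the configured horizon; the ranges
#'   partition the observed MELD domain.
#' @export
extract_strata <- function(tree) {
  leaves <- function(node) {
    if (is.null(node$threshold))
      return(data.frame(meld_lo = node$meld_lo, meld_hi = node$meld_hi,
                        n = node$n, n_events = node$n_events,
                        surv_horizon = node$surv_horizon))
    rbind(leaves(node$left), leaves(node$right))
  }
  leaves(tree)
}

#' @export
print.meld_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$threshold)) {
      cat(sprintf("%sleaf MELD [%d, %d]: n = %d, events = %d, S(h) = %.3f\n",
                  pad, node$meld_lo, node$meld_hi, node$n, node$n_events,
                  node$surv_horizon))
    } else {
      cat(sprintf(
        "%sMELD [%d, %d] (n = %d): split <= %d (chi-sq %.1f, adj p %.3g)\n",
        pad, node$meld_lo, node$meld_hi, node$n, node$threshold,
        node$statistic, node$p_adj))
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  cat("Survival tree over MELD (horizon", x$config$horizon_days, "days)\n")
  rec(x, 0)
  invisible(x)
}

# plain-list view (for JSON export by analysis drivers)
tree_as_list <- function(node) {
  out <- node[intersect(names(node),
                        c("n", "meld_lo", "meld_hi", "n_events",
                          "surv_horizon", "threshold", "statistic",
                          "p_value", "p_adj", "n_candidates"))]
  if (!is.null(node$threshold)) {
    out$left <- tree_as_list(node$left)
    out$right <- tree_as_list(node$right)
  }
  out
}
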