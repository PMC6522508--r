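#' The published KONOS HCC exception table
#'
#' HCC candidates with laboratory MELD below 14 receive 4 additional points;
#' those with MELD 14-20 receive 5. No points above the MELD 20 ceiling,
#' where the presence of HCC does not affect waitlist survival.
#'
#' @return An \code{exception_table}: data.frame(meld_lo, meld_hi,
#'   added_points) with a ceiling attribute of 20.
#' @export
konos_exception_table <- function() {
  structure(data.frame(meld_lo = c(6L, 14L), meld_hi = c(13L, 20L),
                       added_points = c(4L, 5L)),
            ceiling = 20L, class = c("exception_table", "data.frame"))
}

#' Compare waitlist survival between an HCC and a non-HCC MELD band
#'
#' Two-group log-rank test (full follow-up) between HCC candidates in
#' \code{hcc_band} and non-HCC candidates in \code{non_hcc_band}, with
#' Kaplan-Meier survival summaries at \code{horizon_days}.
#'
#' @param registry A \code{liver_registry} data.frame.
#' @param hcc_band,non_hcc_band Inclusive integer MELD ranges
#'   \code{c(lo, hi)} within [6, 40].
#' @param horizon_days Summary horizon (days).
#' @return List of class \code{band_comparison}: \code{logrank},
#'   \code{surv_hcc}, \code{surv_non_hcc}, group sizes, bands, horizon.
#' @export
compare_bands <- function(registry, hcc_band, non_hcc_band,
                          horizon_days = 90) {
  if (horizon_days <= 0) stop("horizon_days must be > 0", call. = FALSE)
  reg <- add_meld(registry)
  out <- derive_outcome(reg)
  in_band <- function(m, b) m >= b[1] & m <= b[2]
  a <- reg$hcc & in_band(reg$meld, hcc_band)
  b <- !reg$hcc & in_band(reg$meld, non_hcc_band)
  if (!any(a) || !any(b))
    stop("degenerate input: empty band", call. = FALSE)
  sel <- a | b
  lr <- logrank_test(out$time_days[sel], out$event[sel],
                     ifelse(a[sel], "hcc", "non_hcc"))
  structure(list(
    hcc_band = hcc_band, non_hcc_band = non_hcc_band,
    horizon_days = horizon_days, logrank = lr,
    n_hcc = sum(a), n_non_hcc = sum(b),
    surv_hcc = km_survival_at(km_fit(out$time_days[a], out$event[a]),
                              horizon_days),
    surv_non_hcc = km_survival_at(km_fit(out$time_days[b], out$event[b]),
                                  horizon_days)),
    class = "band_comparison")
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf(
    "HCC MELD [%d, %d] (n = %d) vs non-HCC MELD [%d, %d] (n = %d)\n",
    x$hcc_band[1], x$hcc_band[2], x$n_hcc,
    x$non_hcc_band[1], x$non_hcc_band[2], x$n_non_hcc))
  cat(sprintf("  S(%g d): HCC %.3f, non-HCC %.3f; log-rank p = %.3g\n",
              x$horizon_days, x$surv_hcc, x$surv_non_hcc,
              x$logrank$p_value))
  invisible(x)
}

#' Derive HCC MELD exception points by survival equivalence
#'
#' For each HCC MELD band [a, b] (below the MELD 20 applicability ceiling),
#' candidate offsets delta are evaluated by comparing the band's HCC
#' candidates against non-HCC candidates with MELD in [a + delta, b + delta]
#' (clipped at 40) using the full-follow-up log-rank test. The selected
#' offset maximizes the log-rank p-value among offsets with p >= alpha
#' (survival statistically indistinguishable); when no offset passes, the
#' max-p offset is returned flagged non-equivalent.
#'
#' @inheritParams compare_bands
#' @param hcc_bands List of inclusive MELD ranges, all within the ceiling;
#'   defaults to the published bands [6,13] and [14,20].
#' @param offsets Candidate integer offsets (default 0:10).
#' @param alpha Equivalence screening level.
#' @param horizon_days Horizon for the reported KM summaries.
#' @return An \code{exception_table} with one row per band: added points,
#'   the achieved p-value, and an \code{equivalent} flag.
#' @export
find_exception_points <- function(registry,
                                  hcc_bands = list(c(6L, 13L), c(14L, 20L)),
                                  offsets = 0:10, alpha = 0.05,
                                  horizon_days = 90) {
  ceiling_meld <- 20L
  if (any(vapply(hcc_bands, function(b) b[2], 0) > ceiling_meld))
    stop("hcc_bands must lie at or below the MELD 20 ceiling", call. = FALSE)
  if (!any(registry$hcc))
    stop("degenerate input: cohort contains no HCC records", call. = FALSE)
  if (!any(!registry$hcc))
    stop("degenerate input: cohort contains no non-HCC records",
         call. = FALSE)
  rows <- lapply(hcc_bands, function(band) {
    p <- vapply(offsets, function(d) {
      nb <- c(band[1] + d, min(band[2] + d, 40L))
      if (nb[1] > 40) return(NA_real_)
      cmp <- tryCatch(compare_bands(registry, band, nb, horizon_days),
                      error = function(e) NULL)
      if (is.null(cmp)) NA_real_ else cmp$logrank$p_value
    }, 0)
    if (all(is.na(p)))
      stop("degenerate input: no candidate offset yields overlapping data",
           call. = FALSE)
    pass <- !is.na(p) & p >= alpha
    if (any(pass)) {
      pick <- which(pass)[which.max(p[pass])]
      equivalent <- TRUE
    } else {
      pick <- which.max(p)
      equivalent <- FALSE
    }
    data.frame(meld_lo = band[1], meld_hi = band[2],
               added_points = as.integer(offsets[pick]),
               p_value = p[pick], equivalent = equivalent)
  })
  structure(do.call(rbind, rows), ceiling = ceiling_meld,
            class = c("exception_table", "data.frame"))
}

#' Apply HCC exception points to obtain the allocation MELD
#'
#' HCC candidates whose MELD falls in a table band gain that band's
#' additional points, capped at 40; all other candidates keep their
#' laboratory MELD. Never decreases a score.
#'
#' @param meld Integer laboratory MELD scores in [6, 40]. Vectorized.
#' @param hcc Logical HCC indicators.
#' @param table An \code{exception_table} (default the published KONOS one).
#' @return Integer allocation MELD scores.
#' @examples
#' apply_exception(12, TRUE)   # 12 + 4 = 16
#' apply_exception(18, TRUE)   # 18 + 5 = 23
#' apply_exception(25, TRUE)   # above the ceiling: unchanged
#' @export
apply_exception <- function(meld, hcc, table = konos_exception_table()) {
  if (any(meld < 6 | meld > 40)) stop("meld must be in [6, 40]", call. = FALSE)
  n <- max(length(meld), length(hcc))
  meld <- rep_len(as.integer(meld), n)
  hcc <- rep_len(as.logical(hcc), n)
  out <- meld
  for (i in seq_len(nrow(table))) {
    sel <- hcc & meld >= table$meld_lo[i] & meld <= table$meld_hi[i]
    out[sel] <- pmin(40L, meld[sel] + table$added_points[i])
  }
  out
}
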