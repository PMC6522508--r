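#' Write a plain-text analysis report
#'
#' Renders a Markdown summary of a cohort: the status x MELD band
#' cross-tabulation, Kaplan-Meier survival by MELD band at the 90- and
#' 14-day horizons, the fitted tree's leaf strata (when given) and the HCC
#' exception table (when given). Regenerating from identical inputs yields
#' identical content.
#'
#' @param registry A non-empty \code{liver_registry}.
#' @param tree Optional \code{\link{fit_tree}} result.
#' @param exception_table Optional \code{exception_table}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(registry, tree = NULL, exception_table = NULL,
                         path) {
  if (is.null(registry) || !nrow(registry))
    stop("empty cohort: nothing to report", call. = FALSE)
  reg <- add_meld(registry)
  out <- derive_outcome(reg)
  band <- meld_band(reg$meld)
  s <- summarize_cohort(registry)

  fmt_tab <- function(df) {
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r)
        paste0("| ", paste(trimws(r), collapse = " | "), " |")))
  }

  band_surv <- do.call(rbind, lapply(levels(band), function(b) {
    sel <- band == b
    if (!any(sel)) return(NULL)
    km <- km_fit(out$time_days[sel], out$event[sel])
    data.frame(band = b, n = sum(sel), events = sum(out$event[sel]),
               surv_90d = round(km_survival_at(km, 90), 3),
               surv_14d = round(km_survival_at(km, 14), 3))
  }))

  lines <- c("# Waitlist cohort report", "",
             sprintf("Cohort: n = %d, HCC %.1f%%, MELD %.1f +/- %.1f", s$n,
                     100 * mean(reg$hcc), s$meld_mean, s$meld_sd), "",
             "## Status x MELD band", "",
             fmt_tab(s$status_meld[s$status_meld$status %in%
                                   c("2A", "2B", "3"), ]), "",
             "## Waitlist survival by MELD band", "",
             fmt_tab(band_surv))
  if (!is.null(tree)) {
    st <- extract_strata(tree)
    st$surv_horizon <- round(st$surv_horizon, 3)
    lines <- c(lines, "", sprintf("## Survival-tree strata (%g-day horizon)",
                                  tree$config$horizon_days), "",
               fmt_tab(st))
  }
  if (!is.null(exception_table)) {
    lines <- c(lines, "", "## HCC MELD exception points", "",
               fmt_tab(as.data.frame(exception_table)))
  }
  writeLines(lines, path)
  invisible(path)
}
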