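#' @keywords internal
registry_columns <- function() {
  c(id = "character", age = "numeric", sex = "character",
    blood_type = "character", bmi = "numeric", etiology = "character",
    hcc = "logical", hcc_stage = "character",
    creatinine = "numeric", bilirubin = "numeric", inr = "numeric",
    dialysis_sessions_last_week = "integer", cvvh_24h = "logical",
    ctp_score = "integer", icu_admitted = "logical",
    life_expectancy_lt_7d = "logical", variceal_bleeding = "logical",
    refractory_ascites = "logical", encephalopathy = "logical",
    hepatorenal = "logical", sbp = "logical", fulminant = "logical",
    region = "integer", follow_up_days = "numeric",
    removal_reason = "character")
}

removal_reasons <- function() {
  c("death", "deterioration", "transplant", "improvement", "still_waiting")
}

# per-row invariant checks; returns character vector of problems (with row ids)
registry_problems <- function(df) {
  probs <- character(0)
  bad <- function(which, what) {
    if (any(which, na.rm = TRUE) || anyNA(which))
      # CSV data line numbers: header is line 1
      sprintf("line %d: %s", which(which | is.na(which)) + 1L, what)
    else character(0)
  }
  probs <- c(probs,
    bad(df$creatinine <= 0, "creatinine must be > 0"),
    bad(df$bilirubin <= 0, "bilirubin must be > 0"),
    bad(df$inr <= 0, "inr must be > 0"),
    bad(df$dialysis_sessions_last_week < 0,
        "dialysis_sessions_last_week must be >= 0"),
    bad(df$ctp_score < 5 | df$ctp_score > 15, "ctp_score must be in [5, 15]"),
    bad(!(df$region %in% 1:3), "region must be 1, 2 or 3"),
    bad(df$follow_up_days < 0, "follow_up_days must be >= 0"),
    bad(!(df$removal_reason %in% removal_reasons()),
        "unknown removal_reason"),
    bad(!(df$sex %in% c("M", "F")), "sex must be M or F"),
    bad(!(df$blood_type %in% c("A", "B", "AB", "O")), "invalid blood_type"))
  probs
}

as_registry <- function(df) {
  cols <- names(registry_columns())
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("registry is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[cols]
  probs <- registry_problems(df)
  if (length(probs))
    stop("invalid registry rows:\n", paste(probs, collapse = "\n"),
         call. = FALSE)
  class(df) <- c("liver_registry", "data.frame")
  df
}

#' Read a waitlist registry CSV
#'
#' Reads a candidate registry (one row per waitlist registration) with the
#' documented header: \code{id, age, sex, blood_type, bmi, etiology, hcc,
#' hcc_stage, creatinine, bilirubin, inr, dialysis_sessions_last_week,
#' cvvh_24h, ctp_score, icu_admitted, life_expectancy_lt_7d,
#' variceal_bleeding, refractory_ascites, encephalopathy, hepatorenal, sbp,
#' fulminant, region, follow_up_days, removal_reason}. Comma-separated,
#' UTF-8, header mandatory; \code{removal_reason} as lowercase token. Rows
#' violating the domain invariants are rejected with their CSV line numbers.
#'
#' @param path Path to the CSV file.
#' @return A \code{liver_registry} data.frame (possibly with zero rows).
#' @seealso \code{\link{write_registry}}, \code{\link{simulate_cohort}}
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cc <- registry_columns()
  hdr <- names(utils::read.csv(path, nrows = 1, fileEncoding = "UTF-8"))
  missing <- setdiff(names(cc), hdr)
  if (length(missing))
    stop("registry is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, colClasses = cc[hdr], na.strings = "",
                        fileEncoding = "UTF-8")
  as_registry(df)
}

#' Write a waitlist registry CSV
#'
#' @param registry A \code{liver_registry} data.frame (see
#'   \code{\link{read_registry}} for the schema).
#' @param path Output path.
#' @return The path, invisibly. Round-trips through
#'   \code{\link{read_registry}}.
#' @export
write_registry <- function(registry, path) {
  registry <- as_registry(as.data.frame(registry))
  utils::write.csv(registry, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive the composite waitlist survival outcome
#'
#' The primary endpoint is waitlist survival: removal for death or for
#' clinical deterioration counts as an event (deterioration on the waitlist
#' is almost uniformly fatal without a graft); removal for transplantation or
#' improvement, and administrative end of follow-up, are censorings.
#'
#' @param registry A \code{liver_registry} data.frame.
#' @return A data.frame with columns \code{time_days} and \code{event}
#'   (logical), one row per registration.
#' @export
derive_outcome <- function(registry) {
  if (!all(registry$removal_reason %in% removal_reasons()))
    stop("unknown removal_reason", call. = FALSE)
  if (any(registry$follow_up_days < 0))
    stop("follow_up_days must be >= 0", call. = FALSE)
  data.frame(time_days = registry$follow_up_days,
             event = registry$removal_reason %in% c("death", "deterioration"))
}

#' Add computed MELD columns to a registry
#'
#' Convenience wrapper around \code{\link{compute_meld}} adding
#' \code{meld_raw} and \code{meld} columns.
#'
#' @inheritParams derive_outcome
#' @param formula A \code{\link{meld_formula}}.
#' @return The registry with two extra columns.
#' @export
add_meld <- function(registry, formula = meld_formula()) {
  m <- compute_meld(registry$creatinine, registry$bilirubin, registry$inr,
                    registry$dialysis_sessions_last_week, registry$cvvh_24h,
                    formula)
  registry$meld_raw <- m$raw
  registry$meld <- m$score
  registry
}

#' Add the previous-system status column to a registry
#'
#' @inheritParams derive_outcome
#' @return The registry with a \code{status} factor column (see
#'   \code{\link{classify_status}}).
#' @export
add_status <- function(registry) {
  registry$status <- classify_status(
    ctp_score = registry$ctp_score,
    icu_admitted = registry$icu_admitted,
    life_expectancy_lt_7d = registry$life_expectancy_lt_7d,
    variceal_bleeding = registry$variceal_bleeding,
    refractory_ascites = registry$refractory_ascites,
    encephalopathy = registry$encephalopathy,
    hepatorenal = registry$hepatorenal,
    sbp = registry$sbp,
    hcc_stage_t1_t2 = registry$hcc & registry$hcc_stage %in% c("T1", "T2"),
    fulminant = registry$fulminant)
  registry
}

pct1 <- function(num, den) round(100 * num / den, 1)

#' Summarize a cohort: status-by-MELD cross-tabulation and covariate marginals
#'
#' Computes the MELD score and previous-system status of every registration
#' and returns (i) the status x MELD-band cross-tabulation with percentages
#' within status, (ii) the same cross-tabulation split by HCC, and (iii)
#' covariate marginals (sex, blood type, etiology, CTP class, HCC) together
#' with the MELD mean and SD.
#'
#' @inheritParams derive_outcome
#' @return An object of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(registry) {
  registry <- add_status(add_meld(as_registry(as.data.frame(registry))))
  band <- meld_band(registry$meld)
  tab <- table(status = registry$status, band = band)
  status_meld <- as.data.frame(tab, responseName = "n")
  tot <- rowSums(tab)[as.character(status_meld$status)]
  status_meld$pct_within_status <- ifelse(tot > 0,
                                          round(100 * status_meld$n / tot, 1),
                                          NA_real_)
  status_hcc_meld <- as.data.frame(
    table(status = registry$status, hcc = registry$hcc, band = band),
    responseName = "n")
  marg <- function(x) {
    t <- table(x)
    data.frame(level = names(t), n = as.integer(t),
               pct = pct1(as.integer(t), length(x)))
  }
  ctp_class <- cut(registry$ctp_score, c(4, 6, 9, 15),
                   labels = c("A", "B", "C"))
  out <- list(
    n = nrow(registry),
    status_meld = status_meld,
    status_hcc_meld = status_hcc_meld,
    covariates = list(sex = marg(registry$sex),
                      blood_type = marg(registry$blood_type),
                      etiology = marg(registry$etiology),
                      ctp_class = marg(ctp_class),
                      hcc = marg(registry$hcc)),
    meld_mean = mean(registry$meld),
    meld_sd = stats::sd(registry$meld),
    age_mean = mean(registry$age),
    follow_up_mean = mean(registry$follow_up_days))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Waitlist cohort summary: n =", x$n, "\n")
  cat(sprintf("  MELD %.1f +/- %.1f, age %.1f, mean follow-up %.0f days\n",
              x$meld_mean, x$meld_sd, x$age_mean, x$follow_up_mean))
  hcc <- x$covariates$hcc
  if ("TRUE" %in% hcc$level)
    cat(sprintf("  HCC: %d (%.1f%%)\n", hcc$n[hcc$level == "TRUE"],
                hcc$pct[hcc$level == "TRUE"]))
  cat("\nStatus x MELD band (n, % within status):\n")
  wide <- stats::reshape(x$status_meld[c("status", "band", "n")],
                         idvar = "status", timevar = "band",
                         direction = "wide")
  names(wide) <- sub("^n\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
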