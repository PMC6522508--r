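#' Classify candidates under the previous CTP-based Korean allocation system
#'
#' Reproduces the pre-2016 KONOS urgency statuses (UNOS-derived):
#' \itemize{
#'   \item \strong{1}: fulminant hepatic failure or early graft failure.
#'   \item \strong{2A}: CTP >= 10, hospitalized in an ICU with a life
#'     expectancy under 7 days, and at least one of life-threatening variceal
#'     bleeding, refractory ascites/hydrothorax, hepatic encephalopathy, or
#'     hepatorenal syndrome.
#'   \item \strong{2B}: CTP >= 10; or CTP >= 7 with at least one of variceal
#'     bleeding, refractory ascites/hydrothorax, or spontaneous bacterial
#'     peritonitis; or stage T1/T2 hepatocellular carcinoma.
#'   \item \strong{3}: CTP >= 7 without meeting 2B criteria.
#'   \item \strong{unlisted}: none of the above.
#' }
#' Higher urgency wins when several definitions are met (1 > 2A > 2B > 3).
#'
#' @param ctp_score Integer Child-Turcotte-Pugh score in [5, 15]. Vectorized.
#' @param icu_admitted,life_expectancy_lt_7d,variceal_bleeding,
#'   refractory_ascites,encephalopathy,hepatorenal,sbp,hcc_stage_t1_t2,
#'   fulminant Logical criterion flags (clinical judgments are inputs, not
#'   computed).
#' @return Factor with levels \code{"1","2A","2B","3","unlisted"}.
#' @export
classify_status <- function(ctp_score,
                            icu_admitted = FALSE,
                            life_expectancy_lt_7d = FALSE,
                            variceal_bleeding = FALSE,
                            refractory_ascites = FALSE,
                            encephalopathy = FALSE,
                            hepatorenal = FALSE,
                            sbp = FALSE,
                            hcc_stage_t1_t2 = FALSE,
                            fulminant = FALSE) {
  n <- length(ctp_score)
  if (any(is.na(ctp_score)) || any(ctp_score < 5 | ctp_score > 15))
    stop("ctp_score must be within [5, 15]", call. = FALSE)
  icu_admitted <- rep_len(icu_admitted, n)
  life_expectancy_lt_7d <- rep_len(life_expectancy_lt_7d, n)
  variceal_bleeding <- rep_len(variceal_bleeding, n)
  refractory_ascites <- rep_len(refractory_ascites, n)
  encephalopathy <- rep_len(encephalopathy, n)
  hepatorenal <- rep_len(hepatorenal, n)
  sbp <- rep_len(sbp, n)
  hcc_stage_t1_t2 <- rep_len(hcc_stage_t1_t2, n)
  fulminant <- rep_len(fulminant, n)

  status <- rep("unlisted", n)
  status[ctp_score >= 7] <- "3"
  is_2b <- ctp_score >= 10 |
    (ctp_score >= 7 & (variceal_bleeding | refractory_ascites | sbp)) |
    hcc_stage_t1_t2
  status[is_2b] <- "2B"
  is_2a <- ctp_score >= 10 & icu_admitted & life_expectancy_lt_7d &
    (variceal_bleeding | refractory_ascites | encephalopathy | hepatorenal)
  status[is_2a] <- "2A"
  status[fulminant] <- "1"
  factor(status, levels = c("1", "2A", "2B", "3", "unlisted"))
}
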