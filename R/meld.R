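#' MELD formula constants
#'
#' Container for the coefficients and capping rules of the MELD (Model for
#' End-stage Liver Disease) equation as operated by KONOS:
#' \deqn{MELD = (0.957 \ln Cr + 0.378 \ln Bili + 1.12 \ln INR + 0.643) \times 10}
#' with laboratory values below 1.0 set to 1.0, serum creatinine capped at
#' 4.0 mg/dL (and forced to 4.0 under dialysis), and the integer score capped
#' at 40.
#'
#' @param coef_creatinine,coef_bilirubin,coef_inr Log-linear coefficients.
#' @param intercept Additive constant before scaling.
#' @param scale Multiplier applied to the linear predictor (10).
#' @param lab_floor Lower clamp for all three laboratory values (1.0).
#' @param creatinine_cap Upper clamp for serum creatinine in mg/dL (4.0).
#' @param score_cap Upper clamp for the integer score (40).
#' @return An object of class \code{meld_formula}.
#' @export
meld_formula <- function(coef_creatinine = 0.957, coef_bilirubin = 0.378,
                         coef_inr = 1.12, intercept = 0.643, scale = 10,
                         lab_floor = 1.0, creatinine_cap = 4.0,
                         score_cap = 40L) {
  if (!(lab_floor < creatinine_cap))
    stop("lab_floor must be strictly below creatinine_cap", call. = FALSE)
  structure(list(coef_creatinine = coef_creatinine,
                 coef_bilirubin = coef_bilirubin,
                 coef_inr = coef_inr,
                 intercept = intercept,
                 scale = scale,
                 lab_floor = lab_floor,
                 creatinine_cap = creatinine_cap,
                 score_cap = as.integer(score_cap)),
            class = "meld_formula")
}

# round half away from zero (UNOS convention); base round() is banker's
round_half_up <- function(x) floor(x + 0.5)

#' Effective (dialysis-adjusted, clamped) serum creatinine
#'
#' Applies the KONOS creatinine rules: patients with two or more dialysis
#' sessions within the last week, or 24 h of continuous veno-venous
#' hemodialysis, have creatinine set to 4.0 mg/dL; otherwise creatinine is
#' capped at 4.0 and floored at 1.0.
#'
#' @param creatinine Serum creatinine, mg/dL (> 0). Vectorized.
#' @param dialysis_sessions_last_week Non-negative integer count.
#' @param cvvh_24h Logical, continuous veno-venous hemodialysis >= 24 h.
#' @param formula A \code{\link{meld_formula}}.
#' @return Numeric vector of effective creatinine values in [1, 4] mg/dL.
#' @export
effective_creatinine <- function(creatinine, dialysis_sessions_last_week = 0L,
                                 cvvh_24h = FALSE, formula = meld_formula()) {
  n <- max(length(creatinine), length(dialysis_sessions_last_week),
           length(cvvh_24h))
  creatinine <- rep_len(creatinine, n)
  dialysis_sessions_last_week <- rep_len(dialysis_sessions_last_week, n)
  cvvh_24h <- rep_len(cvvh_24h, n)
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("creatinine must be strictly positive and finite", call. = FALSE)
  if (any(is.na(dialysis_sessions_last_week)) ||
      any(dialysis_sessions_last_week < 0))
    stop("dialysis_sessions_last_week must be a non-negative count",
         call. = FALSE)
  on_dialysis <- dialysis_sessions_last_week >= 2 | as.logical(cvvh_24h)
  cr <- ifelse(on_dialysis, formula$creatinine_cap,
               pmin(creatinine, formula$creatinine_cap))
  pmax(cr, formula$lab_floor)
}

#' Compute MELD scores
#'
#' Evaluates the KONOS MELD equation for one or more candidates, returning
#' both the raw (real-valued) score and the integer allocation score, which is
#' rounded half-up and capped at 40. The raw score is bounded below by 6.43,
#' so the integer score is always in [6, 40].
#'
#' @param creatinine,bilirubin,inr Laboratory values (> 0). Vectorized.
#' @inheritParams effective_creatinine
#' @return A data.frame with columns \code{raw} and \code{score}.
#' @examples
#' compute_meld(1, 1, 1)            # floor case: raw 6.43, score 6
#' compute_meld(8, 5, 2)            # creatinine capped at 4.0 -> score 34
#' @export
compute_meld <- function(creatinine, bilirubin, inr,
                         dialysis_sessions_last_week = 0L, cvvh_24h = FALSE,
                         formula = meld_formula()) {
  n <- max(length(creatinine), length(bilirubin), length(inr),
           length(dialysis_sessions_last_week), length(cvvh_24h))
  bilirubin <- rep_len(bilirubin, n)
  inr <- rep_len(inr, n)
  if (any(!is.finite(bilirubin)) || any(bilirubin <= 0))
    stop("bilirubin must be strictly positive and finite", call. = FALSE)
  if (any(!is.finite(inr)) || any(inr <= 0))
    stop("inr must be strictly positive and finite", call. = FALSE)
  cr <- effective_creatinine(rep_len(creatinine, n),
                             rep_len(dialysis_sessions_last_week, n),
                             rep_len(cvvh_24h, n), formula)
  raw <- formula$scale *
    (formula$coef_creatinine * log(cr) +
     formula$coef_bilirubin * log(pmax(bilirubin, formula$lab_floor)) +
     formula$coef_inr * log(pmax(inr, formula$lab_floor)) +
     formula$intercept)
  score <- as.integer(pmin(formula$score_cap, round_half_up(raw)))
  data.frame(raw = raw, score = score)
}

#' MELD band used throughout the stratification analysis
#'
#' Cuts integer MELD scores into the four reporting bands
#' \code{<=20}, \code{21-30}, \code{31-37}, \code{38-40}.
#'
#' @param meld Integer MELD scores in [6, 40].
#' @return Factor with four levels.
#' @export
meld_band <- function(meld) {
  if (any(!is.na(meld) & (meld < 6 | meld > 40)))
    stop("meld must be in [6, 40]", call. = FALSE)
  cut(meld, breaks = c(5, 20, 30, 37, 40),
      labels = c("<=20", "21-30", "31-37", "38-40"))
}
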