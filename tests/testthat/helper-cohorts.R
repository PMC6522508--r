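# INR giving exactly the requested integer MELD with creatinine = bilirubin = 1
inr_for_meld <- function(meld) exp((meld / 10 - 0.643) / 1.12)

# minimal valid registry rows; every field overridable, vectors recycled
make_registry <- function(n, meld = 15, hcc = FALSE, hcc_stage = NA_character_,
                          ctp_score = 7L, icu = FALSE, life7 = FALSE,
                          varic = FALSE, ascites = FALSE, enceph = FALSE,
                          hrs = FALSE, sbp = FALSE, fulminant = FALSE,
                          sex = "M", region = 1L, follow_up = 100,
                          reason = "still_waiting", blood = "O") {
  df <- data.frame(
    id = sprintf("X%05d", seq_len(n)),
    age = 55, sex = rep_len(sex, n), blood_type = rep_len(blood, n),
    bmi = 24, etiology = "hbv",
    hcc = rep_len(hcc, n), hcc_stage = rep_len(hcc_stage, n),
    creatinine = 1, bilirubin = 1, inr = inr_for_meld(rep_len(meld, n)),
    dialysis_sessions_last_week = 0L, cvvh_24h = FALSE,
    ctp_score = rep_len(as.integer(ctp_score), n),
    icu_admitted = rep_len(icu, n),
    life_expectancy_lt_7d = rep_len(life7, n),
    variceal_bleeding = rep_len(varic, n),
    refractory_ascites = rep_len(ascites, n),
    encephalopathy = rep_len(enceph, n),
    hepatorenal = rep_len(hrs, n), sbp = rep_len(sbp, n),
    fulminant = rep_len(fulminant, n),
    region = rep_len(as.integer(region), n),
    follow_up_days = rep_len(follow_up, n),
    removal_reason = rep_len(reason, n),
    stringsAsFactors = FALSE)
  df
}

# reconstruction of the published cohort margins: 2248 registrations with the
# printed status x MELD band counts (2A: 22/46/47/44, 2B: 968/291/85/51,
# status 3: 694 all <= 20), 1650 males, and the published HCC splits within
# status 2B (730 HCC of which 14 above MELD 30; 665 non-HCC of which 122
# above 30). Band representatives: MELD 15, 25, 34, 39.
printed_cohort <- function() {
  band_meld <- c(15L, 25L, 34L, 39L)
  mk <- function(counts, ...) {
    meld <- rep(band_meld, counts)
    make_registry(length(meld), meld = meld, ...)
  }
  s2a <- mk(c(22L, 46L, 47L, 44L), ctp_score = 11L, icu = TRUE,
            life7 = TRUE, hrs = TRUE)
  hcc_2b <- c(650L, 66L, 9L, 5L)        # sums to 730, 14 above MELD 30
  non_2b <- c(968L, 291L, 85L, 51L) - hcc_2b  # 665, 122 above MELD 30
  s2b_h <- mk(hcc_2b, ctp_score = 10L, hcc = TRUE, hcc_stage = "T2")
  s2b_n <- mk(non_2b, ctp_score = 10L)
  s3 <- mk(c(694L, 0L, 0L, 0L), ctp_score = 7L)
  reg <- rbind(s2a, s2b_h, s2b_n, s3)
  reg$sex <- rep("F", nrow(reg))
  reg$sex[seq_len(1650L)] <- "M"        # 1650/2248 male
  reg$id <- sprintf("P%05d", seq_len(nrow(reg)))
  reg
}

# exponential survival samples with independent exponential censoring
sim_exp_samples <- function(n, hazard, censor = 0) {
  t_ev <- rexp(n) / hazard
  t_cn <- if (censor > 0) rexp(n) / censor else Inf
  data.frame(time = pmin(t_ev, t_cn), event = t_ev <= t_cn)
}
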