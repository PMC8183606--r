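# Independent continuous-mode (expectation-based) evaluation of both
# strategy arms: a direct transcription of the tree with NO integer
# rounding anywhere.  Used as an oracle for the integer-mode engine; the
# two must agree within the bound obtained by propagating +/-0.5 per
# rounded node through the unit costs.
continuous_cea <- function(params) {
  epi <- params$epidemiology
  scr <- params$screening
  sw <- params$sw
  sv <- params$sv
  cc <- params$costs
  a <- cc$screen_test_A
  b <- cc$confirm_consult_B

  affected <- epi$live_births / epi$cah_incidence_denominator
  n_sw <- affected * epi$sw_fraction
  n_sv <- affected - n_sw
  non_aff <- epi$live_births - affected

  # screened arm
  rec_s <- n_sw * epi$clinical_recognition_sw
  unrec_s <- n_sw - rec_s
  hosp_s <- unrec_s * sw$hosp_rate_screened
  icu_s <- hosp_s * sw$icu_rate_screened
  fp <- non_aff * scr$fp_rate
  high <- fp * scr$high_risk_fraction
  low <- fp - high
  ctn <- high * (1 - scr$confirmatory_fp_fraction)
  cfp <- high - ctn
  rtn <- low * (1 - scr$retest_fp_fraction)
  rfp <- low - rtn
  screened_total <-
    rec_s * (a + b) + unrec_s * (a + b) +
    hosp_s * cc$ward_hospitalization +
    icu_s * sw$icu_days_screened * cc$icu_day +
    n_sv * (2 * a + b) +
    (non_aff - fp) * a + ctn * (a + b) + cfp * (a + 2 * b) +
    rtn * 2 * a + rfp * (2 * a + b)

  # unscreened arm
  rec_u <- n_sw * epi$clinical_recognition_sw
  unrec_u <- n_sw - rec_u
  deaths <- unrec_u * epi$sw_mortality_unscreened
  surv <- unrec_u - deaths
  hosp_u <- surv * sw$hosp_rate_unscreened
  icu_u <- hosp_u * sw$icu_rate_unscreened
  sv_rec <- n_sv * epi$clinical_recognition_sv
  sv_unrec <- n_sv - sv_rec
  gh_pp <- sv$gh_dose_ui_per_day * 365 * sv$gh_years /
    cc$gh_ampoule_ui * cc$gh_ampoule_price
  gnrha_pp <- 4 * sv$gnrha_years * cc$gnrha_ampoule_price
  unscreened_total <-
    rec_u * cc$diagnostic_lab +
    hosp_u * cc$ward_hospitalization +
    icu_u * sw$icu_days_unscreened * cc$icu_day +
    (surv - hosp_u) * cc$diagnostic_lab +
    sv_rec * cc$diagnostic_lab +
    sv_unrec * sv$female_fraction * sv$masculinization_rate *
      cc$masculinization +
    sv_unrec * sv$gh_use_rate * gh_pp +
    sv_unrec * sv$gnrha_use_rate * gnrha_pp +
    sv_unrec * cc$diagnostic_lab

  list(screened_total = screened_total, unscreened_total = unscreened_total,
       deaths = deaths)
}

# Propagated rounding bound: every rounded node can move its count by 0.5
# plus rate x (slack of its parent); complements-by-subtraction add the two
# slacks.  The cost bound is the sum of count slacks times the per-unit
# cost of each billed line (+1 cent per rounded line).
rounding_bounds <- function(params) {
  epi <- params$epidemiology
  scr <- params$screening
  sw <- params$sw
  sv <- params$sv
  cc <- params$costs
  a <- cc$screen_test_A
  b <- cc$confirm_consult_B

  s_aff <- 0.5
  s_sw <- 0.5 + epi$sw_fraction * s_aff
  s_sv <- s_aff + s_sw
  s_naff <- s_aff
  s_rec <- 0.5 + epi$clinical_recognition_sw * s_sw
  s_unrec <- s_sw + s_rec
  # screened arm
  s_hosp_s <- 0.5 + sw$hosp_rate_screened * s_unrec
  s_icu_s <- 0.5 + sw$icu_rate_screened * s_hosp_s
  s_fp <- 0.5 + scr$fp_rate * s_naff
  s_tn <- s_naff + s_fp
  s_high <- 0.5 + scr$high_risk_fraction * s_fp
  s_low <- s_fp + s_high
  s_ctn <- 0.5 + (1 - scr$confirmatory_fp_fraction) * s_high
  s_cfp <- s_high + s_ctn
  s_rtn <- 0.5 + (1 - scr$retest_fp_fraction) * s_low
  s_rfp <- s_low + s_rtn
  bound_screened <-
    s_rec * (a + b) + s_unrec * (a + b) +
    s_hosp_s * cc$ward_hospitalization +
    s_icu_s * sw$icu_days_screened * cc$icu_day +
    s_sv * (2 * a + b) +
    s_tn * a + s_ctn * (a + b) + s_cfp * (a + 2 * b) +
    s_rtn * 2 * a + s_rfp * (2 * a + b) + 0.1

  # unscreened arm
  s_deaths <- 0.5 + epi$sw_mortality_unscreened * s_unrec
  s_surv <- s_unrec + s_deaths
  s_hosp_u <- 0.5 + sw$hosp_rate_unscreened * s_surv
  s_icu_u <- 0.5 + sw$icu_rate_unscreened * s_hosp_u
  s_nonhosp <- s_surv + s_hosp_u
  s_svrec <- 0.5 + epi$clinical_recognition_sv * s_sv
  s_svunrec <- s_sv + s_svrec
  s_masc <- 0.5 + sv$female_fraction * sv$masculinization_rate * s_svunrec
  s_gh <- 0.5 + sv$gh_use_rate * s_svunrec
  s_gnrha <- 0.5 + sv$gnrha_use_rate * s_svunrec
  gh_pp <- sv$gh_dose_ui_per_day * 365 * sv$gh_years /
    cc$gh_ampoule_ui * cc$gh_ampoule_price
  gnrha_pp <- 4 * sv$gnrha_years * cc$gnrha_ampoule_price
  bound_unscreened <-
    s_rec * cc$diagnostic_lab +
    s_hosp_u * cc$ward_hospitalization +
    s_icu_u * sw$icu_days_unscreened * cc$icu_day +
    s_nonhosp * cc$diagnostic_lab +
    s_svrec * cc$diagnostic_lab +
    s_masc * cc$masculinization +
    s_gh * gh_pp + s_gnrha * gnrha_pp +
    s_svunrec * cc$diagnostic_lab + 0.1

  list(screened = bound_screened, unscreened = bound_unscreened)
}
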