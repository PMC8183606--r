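#' Cost a hospitalization block
#'
#' SUS pays ward admissions as a flat fee regardless of length of stay, and
#' ICU care per day.  Of `n_at_risk` patients, `hosp_rate` are admitted
#' (rounded half away from zero), `icu_rate` of the admitted go to the ICU
#' (rounded again) for `icu_days` each.
#'
#' @param n_at_risk integer count of patients at risk of hospitalization.
#' @param hosp_rate proportion hospitalized.
#' @param icu_rate proportion of hospitalized admitted to ICU.
#' @param icu_days ICU length of stay, days.
#' @param costs unit-cost block of a `cah_params` object.
#' @return list with `n_at_risk`, `n_hospitalized`, `n_icu`, `icu_days`,
#'   `ward_cost`, `icu_cost`, `cost` (US$, to the cent).
#' @examples
#' hospitalization_block(115, 0.58, 0.30, 9, cah_preset("base")$costs)
#' @export
hospitalization_block <- function(n_at_risk, hosp_rate, icu_rate, icu_days,
                                  costs) {
  stopifnot(n_at_risk >= 0, hosp_rate >= 0, hosp_rate <= 1,
            icu_rate >= 0, icu_rate <= 1, icu_days >= 0)
  n_hosp <- round_half_up(n_at_risk * hosp_rate)
  n_icu <- round_half_up(n_hosp * icu_rate)
  ward_cost <- round_cents(n_hosp * costs$ward_hospitalization)
  icu_cost <- round_cents(n_icu * icu_days * costs$icu_day)
  list(
    n_at_risk = n_at_risk, n_hospitalized = n_hosp, n_icu = n_icu,
    icu_days = icu_days, ward_cost = ward_cost, icu_cost = icu_cost,
    cost = round_cents(ward_cost + icu_cost)
  )
}

#' Cohort cost of growth-hormone therapy
#'
#' Daily dosing over the treatment period, fractional ampoules allowed; the
#' per-patient cost is kept unrounded and only the cohort total is rounded
#' to the cent.  Years are 365 days.
#'
#' @param n_treated integer count of treated patients.
#' @param dose_ui_day mean dose, UI/day.
#' @param years treatment duration, years.
#' @param ampoule_ui UI per ampoule.
#' @param ampoule_price US$ per ampoule.
#' @return cohort cost in US$.
#' @examples
#' gh_cohort_cost(6, 5.9, 3.2, 12, 33.97)  # 117047.03
#' @export
gh_cohort_cost <- function(n_treated, dose_ui_day, years, ampoule_ui,
                           ampoule_price) {
  stopifnot(n_treated >= 0, dose_ui_day >= 0, years >= 0,
            ampoule_ui > 0, ampoule_price >= 0)
  per_patient <- dose_ui_day * 365 * years / ampoule_ui * ampoule_price
  round_cents(n_treated * per_patient)
}

#' Cohort cost of GnRH-analog therapy
#'
#' One 11.25 mg depot ampoule every 3 months, i.e. 4 ampoules per treatment
#' year.
#'
#' @param n_treated integer count of treated patients.
#' @param years treatment duration, years.
#' @param ampoule_price US$ per ampoule.
#' @return cohort cost in US$, rounded to the cent.
#' @examples
#' gnrha_cohort_cost(12, 3.8, 273.75)  # 49932
#' @export
gnrha_cohort_cost <- function(n_treated, years, ampoule_price) {
  stopifnot(n_treated >= 0, years >= 0, ampoule_price >= 0)
  round_cents(n_treated * 4 * years * ampoule_price)
}

#' Long-term therapy costs of unrecognized simple-virilizing cases
#'
#' Without early diagnosis, SV patients develop precocious pseudo-puberty
#' and virilization: a fraction of 46,XX patients are reared as males and
#' undergo the masculinization process, and fractions are treated with GH
#' (compromised predicted height) and GnRHa (precocious puberty).  All
#' unrecognized SV patients additionally incur the diagnostic laboratory
#' panel at eventual diagnosis.
#'
#' @param n_unrecognized_sv integer count of SV cases missed at birth.
#' @param sv SV-pathway block of a `cah_params` object.
#' @param costs unit-cost block of a `cah_params` object.
#' @return ledger data frame (`node_label`, `count`, `unit_cost_label`,
#'   `cost_usd`) with rows masculinization, GH, GnRHa, diagnostic lab.
#' @export
sv_long_term_costs <- function(n_unrecognized_sv, sv, costs) {
  stopifnot(n_unrecognized_sv >= 0)
  n <- n_unrecognized_sv
  n_masc <- round_half_up(n * sv$female_fraction * sv$masculinization_rate)
  n_gh <- round_half_up(n * sv$gh_use_rate)
  n_gnrha <- round_half_up(n * sv$gnrha_use_rate)
  data.frame(
    node_label = c("masculinization", "gh", "gnrha", "diagnostic_lab"),
    count = c(n_masc, n_gh, n_gnrha, n),
    unit_cost_label = c("masculinization", "gh_ampoule", "gnrha_ampoule",
                        "diagnostic_lab"),
    cost_usd = c(
      round_cents(n_masc * costs$masculinization),
      gh_cohort_cost(n_gh, sv$gh_dose_ui_per_day, sv$gh_years,
                     costs$gh_ampoule_ui, costs$gh_ampoule_price),
      gnrha_cohort_cost(n_gnrha, sv$gnrha_years, costs$gnrha_ampoule_price),
      round_cents(n * costs$diagnostic_lab)
    ),
    stringsAsFactors = FALSE
  )
}
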