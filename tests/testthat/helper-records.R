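# Build a patient-record data frame with sensible defaults, so tests can
# state only the fields they care about.
make_records <- function(n, form = "SW", cohort = "unscreened",
                         sex_karyotype = "46XX", birth_group = "post1999",
                         recognized_early = FALSE, dehydrated = FALSE,
                         hospitalized = FALSE, icu = FALSE,
                         icu_days = NA_real_, sodium = 130,
                         age_at_diagnosis = 30, gh_treated = FALSE,
                         gh_years = 0, gnrha_treated = FALSE,
                         gnrha_years = 0, reared_male_46xx = FALSE) {
  data.frame(
    cohort = rep_len(cohort, n), form = rep_len(form, n),
    sex_karyotype = rep_len(sex_karyotype, n),
    birth_group = rep_len(birth_group, n),
    recognized_early = rep_len(recognized_early, n),
    dehydrated = rep_len(dehydrated, n),
    hospitalized = rep_len(hospitalized, n),
    icu = rep_len(icu, n), icu_days = rep_len(icu_days, n),
    sodium = rep_len(sodium, n),
    age_at_diagnosis = rep_len(age_at_diagnosis, n),
    gh_treated = rep_len(gh_treated, n), gh_years = rep_len(gh_years, n),
    gnrha_treated = rep_len(gnrha_treated, n),
    gnrha_years = rep_len(gnrha_years, n),
    reared_male_46xx = rep_len(reared_male_46xx, n),
    stringsAsFactors = FALSE
  )
}

# n records of which k carry a TRUE flag in the named column
flagged_records <- function(n, k, flag, form = "SW", ...) {
  rec <- make_records(n, form = form, ...)
  rec[[flag]][seq_len(k)] <- TRUE
  # keep the conditional chain consistent
  if (flag %in% c("hospitalized", "icu")) rec$dehydrated[seq_len(k)] <- TRUE
  if (flag == "icu") rec$hospitalized[seq_len(k)] <- TRUE
  rec
}
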