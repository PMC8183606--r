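#' @title Cohort summary statistics and parameter estimators
#' @description
#' Functions that turn patient-level cohort tables into the decision
#' model's input parameters and into the screened-vs-unscreened comparison
#' statistics: means with t-based 95% CIs, proportions with Wilson score
#' intervals, the SW-frequency-deficit mortality estimator, clinical
#' recognition rates, and two-group comparisons (Welch t / chi-square /
#' Fisher).
#' @name cohort-stats
NULL

mean_ci <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(list(mean = NA_real_, lo = NA_real_, hi = NA_real_,
                          n = 0L, available = FALSE))
  m <- mean(x)
  if (n < 2) return(list(mean = m, lo = NA_real_, hi = NA_real_, n = n,
                         available = TRUE))
  half <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  list(mean = m, lo = m - half, hi = m + half, n = as.integer(n),
       available = TRUE)
}

# Wilson score interval: standard for small-sample screening proportions
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(list(p = NA_real_, lo = NA_real_, hi = NA_real_,
                          k = 0L, n = 0L, available = FALSE))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(p = p, lo = max(0, center - half), hi = min(1, center + half),
       k = as.integer(k), n = as.integer(n), available = TRUE)
}

#' Summarize a patient cohort
#'
#' Computes the statistics the decision model consumes: means with
#' t-distribution 95% CIs for sodium, age at diagnosis and ICU stay;
#' proportions (with Wilson 95% CIs) for the SW conditional chain
#' (crisis/dehydration among SW, hospitalization among dehydrated, ICU
#' among hospitalized), early recognition by form, and SV therapy use.
#' Statistics whose subset is empty are marked unavailable (`NA`), never
#' zero.
#'
#' @param records patient-record data frame (see [generate_cohort()] for
#'   the schema).
#' @param subset optional logical vector selecting the rows to summarize.
#' @return a `cohort_summary` list: `n`, `n_sw`, `n_sv`, `mean_sodium`,
#'   `mean_age_at_diagnosis`, `mean_icu_days` (each `list(mean, lo, hi,
#'   n)`), and proportions `prop_dehydrated_sw`,
#'   `prop_hospitalized_dehydrated`, `prop_hospitalized_sw`,
#'   `prop_icu_among_hospitalized`, `prop_recognized_sw`,
#'   `prop_recognized_sv`, `prop_gh_sv`, `prop_gnrha_sv` (each `list(p, lo,
#'   hi, k, n)`).
#' @export
summarize_cohort <- function(records, subset = NULL) {
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  sw <- records[records$form == "SW", , drop = FALSE]
  sv <- records[records$form == "SV", , drop = FALSE]
  dehydrated <- sw[sw$dehydrated, , drop = FALSE]
  hospitalized <- records[records$hospitalized, , drop = FALSE]
  out <- list(
    n = nrow(records), n_sw = nrow(sw), n_sv = nrow(sv),
    mean_sodium = mean_ci(records$sodium),
    mean_age_at_diagnosis = mean_ci(records$age_at_diagnosis),
    mean_icu_days = mean_ci(records$icu_days[records$icu]),
    prop_dehydrated_sw = wilson_ci(sum(sw$dehydrated), nrow(sw)),
    prop_hospitalized_dehydrated =
      wilson_ci(sum(dehydrated$hospitalized), nrow(dehydrated)),
    prop_hospitalized_sw = wilson_ci(sum(sw$hospitalized), nrow(sw)),
    prop_icu_among_hospitalized =
      wilson_ci(sum(hospitalized$icu), nrow(hospitalized)),
    prop_recognized_sw = wilson_ci(sum(sw$recognized_early), nrow(sw)),
    prop_recognized_sv = wilson_ci(sum(sv$recognized_early), nrow(sv)),
    prop_gh_sv = wilson_ci(sum(sv$gh_treated), nrow(sv)),
    prop_gnrha_sv = wilson_ci(sum(sv$gnrha_treated), nrow(sv))
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "(SW", x$n_sw, "/ SV", x$n_sv, ")\n")
  fmt_m <- function(s, lab) {
    if (!s$available) return(cat(" ", lab, ": unavailable\n"))
    cat(sprintf("  %s: %.1f (95%% CI %.1f-%.1f, n=%d)\n", lab, s$mean,
                s$lo, s$hi, s$n))
  }
  fmt_m(x$mean_sodium, "sodium mEq/L")
  fmt_m(x$mean_age_at_diagnosis, "age at diagnosis (d)")
  fmt_m(x$mean_icu_days, "ICU stay (d)")
  fmt_p <- function(s, lab) {
    if (!s$available) return(cat(" ", lab, ": unavailable\n"))
    cat(sprintf("  %s: %.0f%% (%d/%d)\n", lab, 100 * s$p, s$k, s$n))
  }
  fmt_p(x$prop_dehydrated_sw, "SW crisis")
  fmt_p(x$prop_hospitalized_dehydrated, "hospitalized | dehydrated")
  fmt_p(x$prop_icu_among_hospitalized, "ICU | hospitalized")
  invisible(x)
}

#' SW mortality from the salt-wasting frequency deficit
#'
#' In unscreened cohorts, SW infants who die before diagnosis never enter
#' the case series, depressing the observed SW fraction below the one seen
#' under screening; the difference estimates the SW mortality without
#' screening.  Floored at zero.
#'
#' @param sw_fraction_screened SW fraction observed under screening
#'   (reference, e.g. 0.75).
#' @param sw_fraction_unscreened SW fraction observed in the clinical
#'   cohort.
#' @return estimated mortality proportion.
#' @examples
#' estimate_sw_mortality_from_deficit(0.75, 0.64)  # 0.11
#' @export
estimate_sw_mortality_from_deficit <- function(sw_fraction_screened,
                                               sw_fraction_unscreened) {
  stopifnot(sw_fraction_screened >= 0, sw_fraction_screened <= 1,
            sw_fraction_unscreened >= 0, sw_fraction_unscreened <= 1)
  max(0, sw_fraction_screened - sw_fraction_unscreened)
}

#' Clinical recognition rate by form
#'
#' SW: the fraction diagnosed before a salt-wasting crisis (one minus the
#' crisis fraction).  SV: the fraction diagnosed within the first 30 days
#' of life.  Both are carried by the `recognized_early` flag of the record
#' schema.
#'
#' @param records patient-record data frame.
#' @param form `"SW"` or `"SV"`.
#' @return proportion recognized early.
#' @export
clinical_recognition_rate <- function(records, form = c("SW", "SV")) {
  form <- match.arg(form)
  sel <- records[records$form == form, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no records of form '", form, "'", call. = FALSE)
  mean(sel$recognized_early)
}

.compare_continuous <- c("sodium", "age_at_diagnosis", "icu_days")
.compare_flags <- c("recognized_early", "dehydrated", "hospitalized",
                    "icu", "gh_treated", "gnrha_treated")

#' Compare two patient cohorts
#'
#' Continuous variables are compared by Welch's (unequal-variance) t-test
#' on the difference of means; binary variables by the Pearson chi-square
#' test on the 2x2 table, substituting Fisher's exact test for the p-value
#' when any expected cell count falls below 5.  The uncorrected chi-square
#' statistic is always reported.  All tests are two-sided at the 0.05
#' level.
#'
#' @param a,b patient-record data frames (non-empty).
#' @param variables columns to compare; defaults to the record schema's
#'   continuous variables and flags present in both cohorts.
#' @return data frame with one row per variable: `variable`, `type`,
#'   `estimate_a`, `estimate_b`, `difference`, `statistic`, `p_value`,
#'   `test`, `significant`.
#' @export
compare_cohorts <- function(a, b, variables = NULL) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  if (is.null(variables)) {
    variables <- intersect(c(.compare_continuous, .compare_flags),
                           intersect(names(a), names(b)))
  }
  missing_vars <- setdiff(variables, intersect(names(a), names(b)))
  if (length(missing_vars))
    stop("variable(s) absent from a cohort: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  rows <- lapply(variables, function(v) {
    xa <- a[[v]]
    xb <- b[[v]]
    if (is.logical(xa)) {
      ka <- sum(xa, na.rm = TRUE); na <- sum(!is.na(xa))
      kb <- sum(xb, na.rm = TRUE); nb <- sum(!is.na(xb))
      tab <- matrix(c(ka, na - ka, kb, nb - kb), nrow = 2, byrow = TRUE)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(
          stats::chisq.test(tab, correct = FALSE)$p.value)
        test <- "chi-square"
      }
      data.frame(variable = v, type = "proportion",
                 estimate_a = ka / na, estimate_b = kb / nb,
                 difference = ka / na - kb / nb,
                 statistic = unname(stat), p_value = p, test = test,
                 stringsAsFactors = FALSE)
    } else {
      xa <- xa[!is.na(xa)]
      xb <- xb[!is.na(xb)]
      if (length(xa) < 2 || length(xb) < 2) {
        return(data.frame(variable = v, type = "mean",
                          estimate_a = mean(xa), estimate_b = mean(xb),
                          difference = mean(xa) - mean(xb),
                          statistic = NA_real_, p_value = NA_real_,
                          test = "welch-t", stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(xa, xb)
      data.frame(variable = v, type = "mean",
                 estimate_a = mean(xa), estimate_b = mean(xb),
                 difference = mean(xa) - mean(xb),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 test = "welch-t", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  rownames(out) <- NULL
  out
}

#' Derive decision-model parameters from patient cohorts
#'
#' Maps cohort statistics onto the model's parameter fields:
#' hospitalization/ICU rates and ICU durations for both strategies,
#' clinical recognition rates by form, and SW mortality via the
#' SW-frequency-deficit estimator applied to the recent (born 1990 or
#' later) part of the unscreened cohort against the screened SW fraction.
#' Where external (previously published) estimates are supplied, the
#' returned value is the average of the cohort estimate and the external
#' one — the convention used to set the base-case recognition and
#' mortality parameters; fields without a partner estimate are returned
#' raw.
#'
#' @param unscreened,screened patient-record data frames.
#' @param averaging_partner optional named list of external estimates for
#'   any of `clinical_recognition_sw`, `clinical_recognition_sv`,
#'   `sw_mortality_unscreened`.
#' @param sw_fraction_reference SW fraction assumed under screening for
#'   the mortality deficit (default 0.75).
#' @return named list of parameter estimates (a partial `cah_params`
#'   content): `clinical_recognition_sw`, `clinical_recognition_sv`,
#'   `sw_mortality_unscreened`, `hosp_rate_unscreened`,
#'   `icu_rate_unscreened`, `icu_days_unscreened`, `hosp_rate_screened`,
#'   `icu_rate_screened`, `icu_days_screened`.
#' @export
params_from_cohorts <- function(unscreened, screened,
                                averaging_partner = NULL,
                                sw_fraction_reference = 0.75) {
  stopifnot(nrow(unscreened) > 0, nrow(screened) > 0)
  s_un <- summarize_cohort(unscreened)
  s_sc <- summarize_cohort(screened)
  recent <- unscreened[unscreened$birth_group != "pre1990", , drop = FALSE]
  sw_fraction_recent <- if (nrow(recent)) mean(recent$form == "SW") else
    mean(unscreened$form == "SW")

  est <- list(
    clinical_recognition_sw = s_un$prop_recognized_sw$p,
    clinical_recognition_sv = s_un$prop_recognized_sv$p,
    sw_mortality_unscreened = estimate_sw_mortality_from_deficit(
      sw_fraction_reference, sw_fraction_recent),
    hosp_rate_unscreened = s_un$prop_hospitalized_dehydrated$p,
    icu_rate_unscreened = s_un$prop_icu_among_hospitalized$p,
    icu_days_unscreened = s_un$mean_icu_days$mean,
    hosp_rate_screened = s_sc$prop_hospitalized_sw$p,
    icu_rate_screened = s_sc$prop_icu_among_hospitalized$p,
    icu_days_screened = s_sc$mean_icu_days$mean
  )
  for (f in names(averaging_partner)) {
    if (!f %in% names(est))
      stop("no such derivable parameter: '", f, "'", call. = FALSE)
    est[[f]] <- (est[[f]] + averaging_partner[[f]]) / 2
  }
  est
}

#' Screened-cohort descriptive rates from printed integers
#'
#' `incidence_denominator`: the 1:N incidence implied by `cases` confirmed
#' among `screened` newborns.  `first_tier_fp_percent`: the first-tier
#' false-positive rate as a percentage.
#'
#' @param cases confirmed CAH cases.
#' @param screened newborns screened.
#' @param false_positives unaffected newborns with an elevated first-tier
#'   result.
#' @param digits decimals kept on the percentage.
#' @return a number: the incidence denominator (nearest integer), or the
#'   FP percentage.
#' @examples
#' incidence_denominator(25, 378379)           # 15135
#' first_tier_fp_percent(843, 378379)          # 0.22
#' @export
incidence_denominator <- function(cases, screened) {
  stopifnot(cases > 0, screened > 0)
  round_half_up(screened / cases)
}

#' @rdname incidence_denominator
#' @export
first_tier_fp_percent <- function(false_positives, screened, digits = 2) {
  stopifnot(false_positives >= 0, screened > 0)
  round_half_up(100 * false_positives / screened, digits)
}
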