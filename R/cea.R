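#' Evaluate the newborn-screening strategy arm
#'
#' Under screening every affected newborn is detected: clinically recognized
#' SW cases are billed the high-risk screening category (A+B); unrecognized
#' SW cases are billed A+B and, because screening results may arrive after a
#' salt-wasting crisis has begun, still carry a hospitalization block at the
#' screened rates; all SV cases are billed the low-risk category (2A+B) with
#' no long-term adverse outcomes; non-affected newborns flow through the
#' false-positive cascade.  No deaths occur in this arm.
#'
#' @param params a `cah_params` object.
#' @return an `arm_ledger`: list with `strategy`, `items` (data frame
#'   `node_label`, `count`, `unit_cost_label`, `cost_usd`), `total_cost`,
#'   `deaths`, plus the intermediate `partition`, `cascade` and
#'   `hospitalization` pieces.
#' @export
evaluate_screened_arm <- function(params) {
  validate_params(params)
  epi <- params$epidemiology
  part <- partition_birth_cohort(epi$live_births, cah_incidence(params),
                                 epi$sw_fraction)
  sw_recognized <- round_half_up(part$sw * epi$clinical_recognition_sw)
  sw_unrecognized <- part$sw - sw_recognized

  hosp <- hospitalization_block(sw_unrecognized,
                                params$sw$hosp_rate_screened,
                                params$sw$icu_rate_screened,
                                params$sw$icu_days_screened,
                                params$costs)
  cascade <- run_cascade(part$non_affected, params$screening)
  cascade_items <- cascade_costs(cascade, params$costs)

  items <- rbind(
    ledger_row("sw_recognized_screening", sw_recognized, "A+B",
               round_cents(sw_recognized *
                             category_unit_cost("A+B", params$costs))),
    ledger_row("sw_unrecognized_screening", sw_unrecognized, "A+B",
               round_cents(sw_unrecognized *
                             category_unit_cost("A+B", params$costs))),
    ledger_row("sw_unrecognized_hospitalization", hosp$n_hospitalized,
               "ward+icu", hosp$cost),
    ledger_row("sv_screening", part$sv, "2A+B",
               round_cents(part$sv * category_unit_cost("2A+B",
                                                        params$costs))),
    cascade_items
  )
  new_arm_ledger("screened", items, deaths = 0,
                 partition = part, cascade = cascade, hospitalization = hosp,
                 sw_recognized = sw_recognized,
                 sw_unrecognized = sw_unrecognized)
}

#' Evaluate the clinical-diagnosis (non-screening) strategy arm
#'
#' Without screening, recognized cases (genital atypia at birth or family
#' history) incur only the diagnostic laboratory panel.  Unrecognized SW
#' cases die at the SW mortality rate (rounded); deaths incur no cost;
#' survivors are hospitalized at the unscreened rates, with non-hospitalized
#' survivors billed the diagnostic panel.  Unrecognized SV cases incur the
#' long-term therapy ledger.  No screening costs appear anywhere.
#'
#' @param params a `cah_params` object.
#' @return an `arm_ledger`; see [evaluate_screened_arm()].
#' @export
evaluate_unscreened_arm <- function(params) {
  validate_params(params)
  epi <- params$epidemiology
  part <- partition_birth_cohort(epi$live_births, cah_incidence(params),
                                 epi$sw_fraction)
  lab <- params$costs$diagnostic_lab

  sw_recognized <- round_half_up(part$sw * epi$clinical_recognition_sw)
  sw_unrecognized <- part$sw - sw_recognized
  deaths <- round_half_up(sw_unrecognized * epi$sw_mortality_unscreened)
  survivors <- sw_unrecognized - deaths
  hosp <- hospitalization_block(survivors,
                                params$sw$hosp_rate_unscreened,
                                params$sw$icu_rate_unscreened,
                                params$sw$icu_days_unscreened,
                                params$costs)
  not_hospitalized <- survivors - hosp$n_hospitalized

  sv_recognized <- round_half_up(part$sv * epi$clinical_recognition_sv)
  sv_unrecognized <- part$sv - sv_recognized
  sv_items <- sv_long_term_costs(sv_unrecognized, params$sv, params$costs)
  sv_items$node_label <- paste0("sv_unrecognized_", sv_items$node_label)

  items <- rbind(
    ledger_row("sw_recognized_lab", sw_recognized, "diagnostic_lab",
               round_cents(sw_recognized * lab)),
    ledger_row("sw_unrecognized_deaths", deaths, "none", 0),
    ledger_row("sw_unrecognized_hospitalization", hosp$n_hospitalized,
               "ward+icu", hosp$cost),
    ledger_row("sw_dehydrated_not_hospitalized_lab", not_hospitalized,
               "diagnostic_lab", round_cents(not_hospitalized * lab)),
    ledger_row("sv_recognized_lab", sv_recognized, "diagnostic_lab",
               round_cents(sv_recognized * lab)),
    sv_items
  )
  new_arm_ledger("unscreened", items, deaths = deaths,
                 partition = part, hospitalization = hosp,
                 sw_recognized = sw_recognized,
                 sw_unrecognized = sw_unrecognized,
                 sv_recognized = sv_recognized,
                 sv_unrecognized = sv_unrecognized)
}

ledger_row <- function(label, count, unit_label, cost) {
  data.frame(node_label = label, count = count, unit_cost_label = unit_label,
             cost_usd = cost, stringsAsFactors = FALSE)
}

new_arm_ledger <- function(strategy, items, deaths, ...) {
  structure(
    c(list(strategy = strategy, items = items,
           total_cost = round_cents(sum(items$cost_usd)), deaths = deaths),
      list(...)),
    class = "arm_ledger")
}

#' @export
print.arm_ledger <- function(x, ...) {
  cat("<arm_ledger>", x$strategy, "strategy\n")
  print(x$items, row.names = FALSE)
  cat(sprintf("total cost US$ %s, deaths %d\n",
              format(x$total_cost, big.mark = ",", nsmall = 2), x$deaths))
  invisible(x)
}

#' Discounted life-years saved per death averted
#'
#' Converts a death averted at birth into discounted life-years.  The
#' published model adopts the constant 30.2 LY (3% discount on 76 years of
#' life expectancy); the annuity conventions are provided for comparison —
#' the present value of one life-year per year over `life_expectancy` years,
#' paid at the end (`annuity_ordinary`) or start (`annuity_due`) of each
#' year.
#'
#' @param life_expectancy years of life expectancy at birth.
#' @param rate annual discount rate (proportion, e.g. 0.03).
#' @param convention `"constant"` (default), `"annuity_ordinary"` or
#'   `"annuity_due"`.
#' @param constant_value life-years returned under the constant convention.
#' @return discounted life-years.
#' @examples
#' discounted_life_years(76, 0.03)                         # 30.2
#' discounted_life_years(76, 0.03, "annuity_ordinary")     # 29.81...
#' @export
discounted_life_years <- function(life_expectancy, rate,
                                  convention = c("constant",
                                                 "annuity_ordinary",
                                                 "annuity_due"),
                                  constant_value = 30.2) {
  convention <- match.arg(convention)
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  stopifnot(life_expectancy > 0)
  if (convention == "constant") return(constant_value)
  ordinary <- if (rate == 0) life_expectancy else
    (1 - (1 + rate)^(-life_expectancy)) / rate
  if (convention == "annuity_ordinary") ordinary else ordinary * (1 + rate)
}

#' Incremental cost-effectiveness of screening vs clinical diagnosis
#'
#' @param screened,unscreened `arm_ledger` objects from the two evaluators.
#' @param discounted_ly discounted life-years credited per death averted.
#' @return a `cea_result`: list with `incremental_cost`, `deaths_averted`,
#'   `cost_per_death_averted`, `discounted_ly`, `icer` (US$/LY) and
#'   `undefined` (TRUE when no deaths are averted, in which case the ratios
#'   are `NA` — cost-effectiveness is not assessable on this effect
#'   measure).  Monetary outputs are rounded to the cent.
#' @export
incremental_analysis <- function(screened, unscreened, discounted_ly) {
  deaths_averted <- unscreened$deaths - screened$deaths
  if (deaths_averted < 0)
    stop("deaths averted is negative; arms passed in the wrong order?",
         call. = FALSE)
  incremental <- round_cents(screened$total_cost - unscreened$total_cost)
  if (deaths_averted == 0) {
    res <- list(incremental_cost = incremental, deaths_averted = 0,
                cost_per_death_averted = NA_real_,
                discounted_ly = discounted_ly, icer = NA_real_,
                undefined = TRUE)
  } else {
    per_death <- round_cents(incremental / deaths_averted)
    res <- list(incremental_cost = incremental,
                deaths_averted = deaths_averted,
                cost_per_death_averted = per_death,
                discounted_ly = discounted_ly,
                icer = round_cents(per_death / discounted_ly),
                undefined = FALSE)
  }
  structure(res, class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  incremental cost  US$ %s\n",
              format(x$incremental_cost, big.mark = ",", nsmall = 2)))
  cat(sprintf("  deaths averted    %d\n", x$deaths_averted))
  if (x$undefined) {
    cat("  cost per death averted / ICER: undefined (no deaths averted)\n")
  } else {
    cat(sprintf("  per death averted US$ %s\n",
                format(x$cost_per_death_averted, big.mark = ",",
                       nsmall = 2)))
    cat(sprintf("  ICER              US$ %s per discounted LY (%.1f LY)\n",
                format(x$icer, big.mark = ","), x$discounted_ly))
  }
  invisible(x)
}

#' Run the full two-arm cost-effectiveness analysis
#'
#' Convenience wrapper: evaluates both strategy arms and the incremental
#' analysis at the parameter set's discounted life-years per death averted.
#'
#' @param params a `cah_params` object.
#' @return list with `params`, `screened`, `unscreened` (arm ledgers) and
#'   `result` (a `cea_result`).
#' @examples
#' cea <- run_cea(cah_preset("base"))
#' cea$result$icer  # 25535.95
#' @export
run_cea <- function(params) {
  screened <- evaluate_screened_arm(params)
  unscreened <- evaluate_unscreened_arm(params)
  result <- incremental_analysis(
    screened, unscreened,
    params$epidemiology$discounted_ly_per_death)
  list(params = params, screened = screened, unscreened = unscreened,
       result = result)
}
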