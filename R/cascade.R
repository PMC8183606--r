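#' Partition the birth cohort into CAH forms
#'
#' Splits a year's live births into affected newborns (then salt-wasting vs
#' simple-virilizing) and non-affected newborns.  Counts are integers:
#' affected and SW are rounded half away from zero, their complements come by
#' subtraction, so the partition identities hold exactly.
#'
#' @param live_births integer, births entering the model.
#' @param incidence probability of classical CAH per live birth
#'   (e.g. `1/12250`).
#' @param sw_fraction proportion of affected newborns with the SW form.
#' @return list with integer counts `affected`, `sw`, `sv`, `non_affected`.
#' @examples
#' partition_birth_cohort(2923535, 1 / 12250, 0.75)
#' @export
partition_birth_cohort <- function(live_births, incidence, sw_fraction) {
  stopifnot(live_births >= 0, incidence >= 0, incidence <= 1,
            sw_fraction >= 0, sw_fraction <= 1)
  affected <- round_half_up(live_births * incidence)
  sw <- round_half_up(affected * sw_fraction)
  list(
    affected = affected,
    sw = sw,
    sv = affected - sw,
    non_affected = live_births - affected
  )
}

#' Run the screening false-positive cascade
#'
#' Non-affected newborns with an elevated first-tier filter-paper 17-OHP are
#' split into a high-risk stream (serum confirmatory test; a residual
#' fraction remains inconclusive and needs a second confirmatory test) and a
#' low-risk stream (filter-paper retest; a residual fraction stays positive
#' and proceeds to confirmatory testing).  At every split the
#' dismissed/negative branch is rounded half away from zero and the positive
#' remainder obtained by subtraction, so all conservation identities hold
#' exactly.
#'
#' @param non_affected integer count of newborns without CAH.
#' @param perf screening-performance block of a `cah_params` object (list
#'   with `fp_rate`, `high_risk_fraction`, `confirmatory_fp_fraction`,
#'   `retest_fp_fraction`).
#' @return list of integer counts: `true_negative`, `fp_total`, `fp_high`,
#'   `fp_low`, `confirm_tn`, `confirm_fp`, `retest_tn`, `retest_fp`.
#' @examples
#' run_cascade(2923296, cah_preset("base")$screening)
#' @export
run_cascade <- function(non_affected, perf) {
  stopifnot(non_affected >= 0)
  fp_total <- round_half_up(non_affected * perf$fp_rate)
  fp_high <- round_half_up(fp_total * perf$high_risk_fraction)
  fp_low <- fp_total - fp_high
  confirm_tn <- round_half_up(fp_high * (1 - perf$confirmatory_fp_fraction))
  retest_tn <- round_half_up(fp_low * (1 - perf$retest_fp_fraction))
  list(
    true_negative = non_affected - fp_total,
    fp_total = fp_total,
    fp_high = fp_high,
    fp_low = fp_low,
    confirm_tn = confirm_tn,
    confirm_fp = fp_high - confirm_tn,
    retest_tn = retest_tn,
    retest_fp = fp_low - retest_tn
  )
}

#' Per-child screening cost of a billing category
#'
#' Categories combine the filter-paper test (A) and the confirmatory labs +
#' consultation bundle (B): `A` one screen; `2A` screen plus retest; `A+B`
#' screen plus confirmation; `2A+B` screen, retest and confirmation; `A+2B`
#' screen plus two confirmatory rounds.
#'
#' @param label one of `"A"`, `"2A"`, `"A+B"`, `"2A+B"`, `"A+2B"`.
#' @param costs unit-cost block of a `cah_params` object.
#' @return US$ per child, rounded to the cent.
#' @examples
#' category_unit_cost("A+B", cah_preset("base")$costs)  # 24.91
#' @export
category_unit_cost <- function(label, costs) {
  a <- costs$screen_test_A
  b <- costs$confirm_consult_B
  value <- switch(label,
    "A" = a,
    "2A" = 2 * a,
    "A+B" = a + b,
    "2A+B" = 2 * a + b,
    "A+2B" = a + 2 * b,
    stop("unknown cost category '", label,
         "'; valid: A, 2A, A+B, 2A+B, A+2B", call. = FALSE)
  )
  round_cents(value)
}

#' Itemized screening costs of the false-positive cascade
#'
#' @param counts cascade counts from [run_cascade()].
#' @param costs unit-cost block of a `cah_params` object.
#' @return data frame with columns `node_label`, `count`, `unit_cost_label`,
#'   `cost_usd`; one row per billed node, each rounded to the cent.
#' @export
cascade_costs <- function(counts, costs) {
  nodes <- data.frame(
    node_label = c("true_negative", "confirm_tn", "confirm_fp",
                   "retest_tn", "retest_fp"),
    count = c(counts$true_negative, counts$confirm_tn, counts$confirm_fp,
              counts$retest_tn, counts$retest_fp),
    unit_cost_label = c("A", "A+B", "A+2B", "2A", "2A+B"),
    stringsAsFactors = FALSE
  )
  nodes$cost_usd <- vapply(seq_len(nrow(nodes)), function(i) {
    round_cents(nodes$count[i] *
                  category_unit_cost(nodes$unit_cost_label[i], costs))
  }, numeric(1))
  nodes
}

#' Export a cost ledger to CSV
#'
#' Writes any ledger data frame with columns `node_label`, `count`,
#' `unit_cost_label`, `cost_usd` (the shared schema of cascade and therapy
#' ledgers) to delimited text.
#'
#' @param ledger ledger data frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_ledger <- function(ledger, file) {
  utils::write.csv(ledger, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
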