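# Full published cost table, all three scenario columns, frozen to the cent.
# Two cells of the source table are internally inconsistent (the SV
# non-screening subtotal and the dehydration-without-hospitalization lab
# line); the expectations below carry the values implied by the table's own
# components and strategy totals.
expected_screened <- list(
  base = c(sw_recognized_screening = 1594.24,
           sw_unrecognized_screening = 2864.65,
           sw_unrecognized_hospitalization = 32805.60,
           sv_screening = 1641.60, true_negative = 7147750.05,
           confirm_tn = 33503.95, confirm_fp = 5542.29,
           retest_tn = 21378.70, retest_fp = 601.92),
  best = c(sw_recognized_screening = 871.85,
           sw_unrecognized_screening = 4583.44,
           sw_unrecognized_hospitalization = 52474.80,
           sv_screening = 1997.28, true_negative = 7154784.00,
           confirm_tn = 16764.43, confirm_fp = 2747.46,
           retest_tn = 10686.90, retest_fp = 300.96),
  worst = c(sw_recognized_screening = 1992.80,
            sw_unrecognized_screening = 1644.06,
            sw_unrecognized_hospitalization = 18124.50,
            sv_screening = 1340.64, true_negative = 7126371.35,
            confirm_tn = 83747.42, confirm_fp = 13832.04,
            retest_tn = 53449.20, retest_fp = 1504.80)
)
expected_unscreened <- list(
  base = c(sw_recognized_lab = 963.20, sw_unrecognized_deaths = 0,
           sw_unrecognized_hospitalization = 132296.30,
           sw_dehydrated_not_hospitalized_lab = 150.50,
           sv_recognized_lab = 255.85,
           sv_unrecognized_masculinization = 5718.57,
           sv_unrecognized_gh = 117047.03, sv_unrecognized_gnrha = 49932.00,
           sv_unrecognized_diagnostic_lab = 647.15),
  best = c(sw_recognized_lab = 526.75, sw_unrecognized_deaths = 0,
           sw_unrecognized_hospitalization = 204177.00,
           sw_dehydrated_not_hospitalized_lab = 225.75,
           sv_recognized_lab = 120.40,
           sv_unrecognized_masculinization = 9530.95,
           sv_unrecognized_gh = 175570.55, sv_unrecognized_gnrha = 74898.00,
           sv_unrecognized_diagnostic_lab = 978.25),
  worst = c(sw_recognized_lab = 1204.00, sw_unrecognized_deaths = 0,
            sw_unrecognized_hospitalization = 79335.30,
            sw_dehydrated_not_hospitalized_lab = 90.30,
            sv_recognized_lab = 331.10,
            sv_unrecognized_masculinization = 3812.38,
            sv_unrecognized_gh = 78031.35, sv_unrecognized_gnrha = 33288.00,
            sv_unrecognized_diagnostic_lab = 406.35)
)
expected_totals <- data.frame(
  scenario = c("base", "best", "worst"),
  screened = c(7247683.00, 7245211.12, 7302006.81),
  unscreened = c(307010.60, 466027.65, 196498.78),
  deaths = c(9, 20, 3),
  incremental = c(6940672.40, 6779183.47, 7105508.03),
  per_death = c(771185.82, 338959.17, 2368502.68),
  icer = c(25535.95, 11223.81, 78427.24)
)

test_that("both strategy arms reproduce the published table to the cent", {
  for (i in 1:3) {
    s <- expected_totals$scenario[i]
    params <- cah_preset(s)
    scr <- evaluate_screened_arm(params)
    expect_equal(setNames(scr$items$cost_usd, scr$items$node_label),
                 expected_screened[[s]])
    expect_equal(scr$total_cost, expected_totals$screened[i])
    expect_equal(scr$deaths, 0)

    uns <- evaluate_unscreened_arm(params)
    expect_equal(setNames(uns$items$cost_usd, uns$items$node_label),
                 expected_unscreened[[s]])
    expect_equal(uns$total_cost, expected_totals$unscreened[i])
    expect_equal(uns$deaths, expected_totals$deaths[i])
  }
})

test_that("published interior counts appear in the arm ledgers", {
  uns <- evaluate_unscreened_arm(cah_preset("base"))
  expect_equal(uns$hospitalization$n_hospitalized, 96)
  expect_equal(uns$hospitalization$n_icu, 35)
  scr <- evaluate_screened_arm(cah_preset("base"))
  expect_equal(scr$sw_recognized, 64)
  expect_equal(scr$sw_unrecognized, 115)
  expect_equal(scr$hospitalization$n_hospitalized, 67)
  expect_equal(scr$hospitalization$n_icu, 20)
})

test_that("incremental analysis reproduces the published summary rows", {
  for (i in 1:3) {
    params <- cah_preset(expected_totals$scenario[i])
    res <- run_cea(params)$result
    expect_equal(res$incremental_cost, expected_totals$incremental[i])
    expect_equal(res$deaths_averted, expected_totals$deaths[i])
    expect_equal(res$cost_per_death_averted, expected_totals$per_death[i])
    expect_equal(res$icer, expected_totals$icer[i])
  }
})

test_that("arm totals equal the sum of their line items", {
  set.seed(88)
  params <- cah_preset("base")
  for (i in 1:20) {
    p <- params
    p$epidemiology$sw_mortality_unscreened <- runif(1, 0, 0.3)
    p$epidemiology$clinical_recognition_sw <- runif(1)
    p$screening$fp_rate <- runif(1, 0, 0.02)
    for (arm in list(evaluate_screened_arm(p),
                     evaluate_unscreened_arm(p))) {
      expect_equal(arm$total_cost, round_cents(sum(arm$items$cost_usd)))
    }
  }
})

test_that("discounted life-years follow the stated conventions", {
  expect_equal(discounted_life_years(76, 0.03), 30.2)
  expect_equal(discounted_life_years(76, 0.03, constant_value = 28), 28)
  expect_equal(discounted_life_years(76, 0, "annuity_ordinary"), 76)
  # oracle: present value summed year by year
  pv <- sum((1 + 0.03)^-(1:76))
  expect_equal(discounted_life_years(76, 0.03, "annuity_ordinary"), pv)
  expect_equal(round(pv, 2), 29.81)
  expect_equal(discounted_life_years(76, 0.03, "annuity_due"), pv * 1.03)
  expect_error(discounted_life_years(76, -0.01, "annuity_ordinary"),
               "rate")
})

test_that("zero deaths averted flags the ratios undefined, not numeric", {
  arm <- evaluate_screened_arm(cah_preset("base"))
  res <- incremental_analysis(arm, arm, 30.2)
  expect_equal(res$incremental_cost, 0)
  expect_equal(res$deaths_averted, 0)
  expect_true(res$undefined)
  expect_true(is.na(res$icer))
  expect_true(is.na(res$cost_per_death_averted))
})

test_that("integer-mode totals agree with the continuous oracle within
           the propagated rounding bound", {
  scenarios <- lapply(c("base", "best", "worst", "group3"), cah_preset)
  # and some one-way displaced parameter sets
  for (rg in table_ranges()) {
    scenarios <- c(scenarios,
                   list(apply_range(cah_preset("base"), rg, "low"),
                        apply_range(cah_preset("base"), rg, "high")))
  }
  for (p in scenarios) {
    oracle <- continuous_cea(p)
    bounds <- rounding_bounds(p)
    scr <- evaluate_screened_arm(p)
    uns <- evaluate_unscreened_arm(p)
    expect_lt(abs(scr$total_cost - oracle$screened_total), bounds$screened)
    expect_lt(abs(uns$total_cost - oracle$unscreened_total),
              bounds$unscreened)
    expect_lt(abs(uns$deaths - oracle$deaths), 3)
  }
})

test_that("ICER falls as mortality rises and rises with recognition", {
  base <- cah_preset("base")
  icer_at <- function(p) run_cea(p)$result$icer
  mort <- vapply(c(0.042, 0.08, 0.11), function(m)
    icer_at(param_set(base, "epidemiology.sw_mortality_unscreened", m)),
    numeric(1))
  expect_true(all(diff(mort) < 0))
  rec <- vapply(list(c(0.16, 0.11), c(0.36, 0.28), c(0.55, 0.45)),
                function(r) {
    p <- param_set(base, "epidemiology.clinical_recognition_sw", r[1])
    icer_at(param_set(p, "epidemiology.clinical_recognition_sv", r[2]))
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})
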