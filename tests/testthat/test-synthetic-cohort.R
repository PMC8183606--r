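test_that("generation is deterministic given the seed", {
  truth <- cohort_truth_preset("unscreened", seed = 42)
  a <- generate_cohort(truth)
  b <- generate_cohort(truth)
  expect_identical(a, b)
  c <- generate_cohort(truth, seed = 43)
  expect_false(identical(a, c))
})

test_that("cohort CSVs round-trip through read/write", {
  truth <- cohort_truth_preset("screened", seed = 7)
  rec <- generate_cohort(truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rec, path)
  back <- read_cohort(path)
  expect_equal(back, rec, tolerance = 1e-12)
})

test_that("degenerate probabilities produce degenerate cohorts", {
  truth <- cohort_truth_preset("unscreened", seed = 5)
  truth$crisis_rate_sw <- 1
  rec <- generate_cohort(truth)
  expect_true(all(rec$dehydrated[rec$form == "SW"]))
  truth$crisis_rate_sw <- 0
  rec <- generate_cohort(truth)
  expect_true(!any(rec$dehydrated))
  expect_true(!any(rec$hospitalized))
})

test_that("the conditional flag chain holds in every record", {
  for (which in c("unscreened", "screened", "group3")) {
    for (seed in c(1, 99)) {
      rec <- generate_cohort(cohort_truth_preset(which, seed = seed))
      expect_true(all(rec$hospitalized[rec$icu]))
      expect_true(all(rec$dehydrated[rec$hospitalized]))
      expect_true(!any(rec$dehydrated[rec$form == "SV"]))
      expect_true(all(is.na(rec$icu_days[!rec$icu])))
      expect_true(all(rec$icu_days[rec$icu] > 0))
      expect_true(all(rec$gh_years[rec$gh_treated] > 0))
      expect_true(all(rec$gh_years[!rec$gh_treated] == 0))
      expect_true(all(rec$gnrha_years[!rec$gnrha_treated] == 0))
      expect_true(all(rec$sex_karyotype[rec$reared_male_46xx] == "46XX"))
    }
  }
})

test_that("continuous variables respect their truncation bounds", {
  rec <- generate_cohort(cohort_truth_preset("unscreened", seed = 31),
                         n_sw = 5000, n_sv = 5000)
  expect_true(all(rec$sodium >= 100 & rec$sodium <= 150))
  expect_true(all(rec$age_at_diagnosis >= 0))
  expect_true(all(rec$icu_days[rec$icu] > 0))
  expect_true(all(rec$gh_years >= 0))
})

test_that("large-sample hospitalization rate sits in the 99% binomial
           interval", {
  truth <- cohort_truth_preset("unscreened", seed = 2024)
  rec <- generate_cohort(truth, n_sw = 10000, n_sv = 0)
  dehydrated <- rec[rec$dehydrated, ]
  phat <- mean(dehydrated$hospitalized)
  half <- qnorm(0.995) * sqrt(0.91 * 0.09 / nrow(dehydrated))
  expect_lt(abs(phat - 0.91), half)
})

test_that("summaries recover the generator truths across a 20-seed
           battery at n = 10,000", {
  truth <- cohort_truth_preset("unscreened")
  # per-seed: a gross-error bound at 4 MC SEs (the battery makes ~160
  # binomial checks; a hard 3-SE bound on each would false-alarm on ~30%
  # of seed batteries, 4 SEs keeps the family-wise false-alarm near 1%).
  # pooled: the battery-aggregated estimate must sit within 3 MC SEs of
  # the pooled sample size, the higher-powered recovery check.
  zscore <- function(phat, p, n) (phat - p) / sqrt(p * (1 - p) / n)
  props <- list(
    c("prop_dehydrated_sw", "crisis_rate_sw"),
    c("prop_hospitalized_dehydrated", "hosp_rate_dehydrated"),
    c("prop_icu_among_hospitalized", "icu_rate_hospitalized"),
    c("prop_recognized_sv", "sv_recognition_rate"),
    c("prop_gh_sv", "gh_rate"),
    c("prop_gnrha_sv", "gnrha_rate"))
  pooled_k <- numeric(length(props))
  pooled_n <- numeric(length(props))
  pooled_sodium <- c(sum = 0, n = 0)
  pooled_icu <- c(sum = 0, n = 0)
  for (seed in 1:20) {
    rec <- generate_cohort(truth, n_sw = 10000, n_sv = 10000, seed = seed)
    s <- summarize_cohort(rec)
    for (j in seq_along(props)) {
      st <- s[[props[[j]][1]]]
      expect_lt(abs(zscore(st$p, truth[[props[[j]][2]]], st$n)), 4)
      pooled_k[j] <- pooled_k[j] + st$k
      pooled_n[j] <- pooled_n[j] + st$n
    }
    expect_lt(abs(s$mean_sodium$mean - truth$sodium_mean) /
                ((s$mean_sodium$hi - s$mean_sodium$lo) / (2 * 1.96)), 4)
    expect_lt(abs(s$mean_icu_days$mean - truth$icu_days_mean) /
                ((s$mean_icu_days$hi - s$mean_icu_days$lo) / (2 * 1.96)), 4)
    pooled_sodium <- pooled_sodium +
      c(s$mean_sodium$mean * s$mean_sodium$n, s$mean_sodium$n)
    pooled_icu <- pooled_icu +
      c(s$mean_icu_days$mean * s$mean_icu_days$n, s$mean_icu_days$n)
  }
  for (j in seq_along(props)) {
    expect_lt(abs(zscore(pooled_k[j] / pooled_n[j],
                         truth[[props[[j]][2]]], pooled_n[j])), 3)
  }
  # pooled means within 3 SEs, using the truth SDs for the MC error
  expect_lt(abs(pooled_sodium[1] / pooled_sodium[2] - truth$sodium_mean),
            3 * truth$sodium_sd / sqrt(pooled_sodium[2]))
  expect_lt(abs(pooled_icu[1] / pooled_icu[2] - truth$icu_days_mean),
            3 * truth$icu_days_sd / sqrt(pooled_icu[2]))
})

test_that("truth presets carry the reported cohort statistics", {
  un <- cohort_truth_preset("unscreened")
  expect_equal(un$sodium_mean, 121.2)
  expect_equal(un$icu_days_mean, 23)
  expect_equal(un$hosp_rate_dehydrated, 0.91)
  expect_equal(un$crisis_rate_sw, 0.84)
  expect_equal(un$n_sw + un$n_sv, 195)

  sc <- cohort_truth_preset("screened")
  expect_equal(sc$sodium_mean, 131.8)
  expect_equal(sc$icu_days_mean, 9)
  expect_equal(sc$age_dx_mean, 17.2)

  g3 <- cohort_truth_preset("group3")
  expect_equal(g3$icu_rate_hospitalized, 0.61)
  expect_equal(g3$icu_days_mean, 20)
  expect_equal(g3$n_sw + g3$n_sv, 33)

  expect_error(cohort_truth_preset("group4"))
})

test_that("impossible truths are rejected", {
  expect_error(
    generator_truth(n_sw = 10, n_sv = 10, crisis_rate_sw = 1.2,
                    hosp_rate_dehydrated = 0.9,
                    icu_rate_hospitalized = 0.3, icu_days_mean = 9,
                    icu_days_sd = 1, sodium_mean = 130, sodium_sd = 5,
                    age_dx_mean = 20, age_dx_sd = 5,
                    sv_recognition_rate = 0.1, gh_rate = 0.1,
                    gh_years_mean = 3, gh_years_sd = 1, gnrha_rate = 0.2,
                    gnrha_years_mean = 4, gnrha_years_sd = 1,
                    masculinization_rate = 0.1),
    "crisis_rate_sw")
  expect_error(
    generator_truth(n_sw = 10, n_sv = 10, crisis_rate_sw = 0.8,
                    hosp_rate_dehydrated = 0.9,
                    icu_rate_hospitalized = 0.3, icu_days_mean = 9,
                    icu_days_sd = -1, sodium_mean = 130, sodium_sd = 5,
                    age_dx_mean = 20, age_dx_sd = 5,
                    sv_recognition_rate = 0.1, gh_rate = 0.1,
                    gh_years_mean = 3, gh_years_sd = 1, gnrha_rate = 0.2,
                    gnrha_years_mean = 4, gnrha_years_sd = 1,
                    masculinization_rate = 0.1),
    "sd")
})

test_that("CI-derived standard deviations reproduce the interval", {
  sd <- sd_from_ci(118.3, 124.1, 105)
  half <- qt(0.975, 104) * sd / sqrt(105)
  expect_equal(half, (124.1 - 118.3) / 2)
  expect_gt(sd, 0)
})
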