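---
title: "Cost-effectiveness of CAH newborn screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-effectiveness of CAH newborn screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cahcea)
```

## The decision problem

Classical congenital adrenal hyperplasia (CAH, 21-hydroxylase deficiency)
occurs in roughly 1 in 10,000–15,000 live births.  Three quarters of
classical cases are salt-wasting (SW): without early treatment these
newborns are at risk of a life-threatening adrenal crisis in the first
weeks of life.  The remainder are simple-virilizing (SV): missed at birth,
they develop precocious pseudo-puberty, compromised final height, and —
for 46,XX newborns misassigned as males — the masculinization pathway of
genital surgery and androgen replacement.

Newborn screening (NBS) measures 17-hydroxyprogesterone on the dried-blood
filter paper already collected for other screening programs.  It detects
essentially all classical cases, but at the price of a false-positive
cascade: unaffected newborns with an elevated first-tier result must be
retested (low-risk results, < 2x the cutoff) or referred for serum
confirmatory testing and a specialist consultation (high-risk results).

`cahcea` implements a decision-tree cost-effectiveness model comparing the
screening strategy against clinical diagnosis for one year of Brazilian
live births (2,923,535 in 2017), from the perspective of the public health
system (SUS), which pays ward admissions as a flat fee and ICU care per
day.  Costs are 2016 US$ throughout (the SUS reimbursement schedule
converted at R$ 3.26 per US$; the package performs no currency
arithmetic).  The effect measure is deaths averted, converted to
discounted life-years:

$$
\mathrm{ICER} \;=\;
\frac{C_{\mathrm{NBS}} - C_{\mathrm{clinical}}}
     {\Delta\mathrm{deaths} \times 30.2\ \mathrm{LY}}
\qquad [\mathrm{US\$/LY}]
$$

where 30.2 LY is the discounted life expectancy credited per neonatal
death averted (3% per year over 76 years).

## Model structure

Both arms start from the same partition of the birth cohort: affected
newborns (incidence is stored as the exact rational 1/denominator, e.g.
1:12,250, to avoid decimal drift), split 75%/25% into SW and SV, with the
rest non-affected.

**Screening arm.**  All affected cases are detected.  Clinically
recognized SW cases (genital atypia, family history) are billed the
high-risk screening category A+B (filter-paper test A = US\$ 2.45 plus
confirmatory-labs-and-consultation bundle B = US\$ 22.46); unrecognized SW
cases are billed A+B and still carry a hospitalization block at the
screened rates (58% hospitalized, 30% of those in ICU for 9 days), because
screening results can arrive after a crisis has begun.  All SV cases are
billed the low-risk category 2A+B with no long-term outcomes.  Non-affected
newborns flow through the cascade: 0.2% screen false positive, 25%
high-risk (92% dismissed after one confirmatory test, 8% needing a second,
billed A+2B), 75% low-risk (99.5% dismissed after a retest, billed 2A; the
rest billed 2A+B).  No deaths occur in this arm.

**Clinical-diagnosis arm.**  Recognized cases incur only the diagnostic
laboratory panel (US\$ 15.05).  Unrecognized SW cases die at the SW
mortality rate (8% base case); survivors are hospitalized at the
unscreened rates (91%, 36% ICU, 23 days), and non-hospitalized survivors
are billed the diagnostic panel.  Unrecognized SV cases incur the
long-term ledger: masculinization (15% of the 46,XX half), growth hormone
(14%, 5.9 UI/day for 3.2 years, fractional 12-UI ampoules at US\$ 33.97),
GnRH analog (28%, four 11.25 mg ampoules per year for 3.8 years at
US\$ 273.75 each), plus the diagnostic panel for everyone.

```{r base-case}
cea <- run_cea(cah_preset("base"))
cea$result
```

## Numerical conventions

The published table this model reproduces reports integer patient counts
at every node.  Three conventions, fixed once, reproduce every printed
count and cent across all three scenario columns:

* **Rounding**: every "rate x count" node rounds half *away from zero*
  (`round_half_up()`); the complementary branch is obtained by
  subtraction, which makes every conservation identity exact
  (`fp_high + fp_low = fp_total`, and so on).  A `1e-9` guard absorbs
  binary floating-point representation error at exact `.5` boundaries.
* **Currency**: therapy costs are kept unrounded per patient and rounded
  to the cent only at the cohort-total line; treatment years are 365
  days.  Ampoules are not rounded up to whole units.
* **Order of operations** in the unscreened arm: deaths are subtracted
  from the unrecognized SW count *before* the hospitalization rate is
  applied (the survivor denominator).

Two cells of the source table are internally inconsistent (an SV subtotal
that contradicts its own components, and a lab-cost line off by one digit
transposition); the engine reports the values implied by the table's own
components and totals, which also match the printed strategy totals.

The constant 30.2 LY does not equal the 3%/76-year annuity under either
standard convention — `discounted_life_years(76, 0.03,
"annuity_ordinary")` gives `r round(discounted_life_years(76, 0.03,
"annuity_ordinary"), 2)` and the annuity-due variant `r
round(discounted_life_years(76, 0.03, "annuity_due"), 2)` — so the
constant convention is the default and the annuities are available for
comparison.

## Design choices where the source was silent

* **46,XX fraction of unrecognized SV cases** feeding the masculinization
  node is 0.5 (the sex ratio at birth), exposed as `sv.female_fraction`.
  The published counts (3 of 43, 5 of 65, 2 of 27) are reproduced only by
  0.5, not by the observed cohort's 74% female share, which reflects
  ascertainment bias in a clinically diagnosed series.
* **Confirmatory false positives** (the 8% of high-risk FPs still
  inconclusive after the first serum test) are billed A+2B and incur no
  further downstream cost.
* **No terminal-care cost** attaches to deaths; deceased patients incur
  zero cost.
* Maintenance therapy (hydrocortisone/fludrocortisone) is identical in
  both arms and cancels out of the incremental comparison, so it is not
  modelled.

## Sensitivity machinery

`one_way_sweep()` re-runs the *full integer-rounded engine* at each grid
point — not a linearized approximation — so sweep values are consistent
with the main table's conventions.  The published one-way endpoints were
evidently produced under a different (unrecoverable) evaluation mode;
this engine lands within ~1.2% of each of the eight printed endpoint
ICERs, and the tests hold them to 5% with strict direction checks
(mortality up, ICER down; recognition up, ICER up; incidence up, ICER
down).  The joint SW/SV recognition row is implemented as a *paired
range* moving both parameters together.  `tornado()` orders parameters by
endpoint-ICER span with a lexical tie-break, so the ordering is invariant
to input order.

```{r tornado}
tornado(cah_preset("base"), table_ranges())
```

The published "cohort born from 2000" row is implemented as the named
preset `"group3"` carrying the post-1999 subcohort's observed values
(mortality 5% from the 75%-70% SW-frequency deficit, SW recognition 13%,
hospitalization 90%, ICU 61% for 20 days, GH 40%/3.9 y/5.09 UI, GnRHa
30%/5.1 y, masculinization 11%).  Its ICER is reported but not asserted
against the published value: the generating inputs of that row are not
recoverable from the printed statistics.

## The synthetic cohort generator

The estimators in this package were designed for hospital chart review
data that cannot be redistributed.  `generate_cohort()` produces
patient-level tables with the same statistical structure so that every
estimation stage runs end to end:

* **Flags** follow the conditional chain crisis → hospitalization → ICU
  as Bernoulli draws at the stated conditional rates; the chain
  implications hold in every generated record, by construction.
* **Continuous variables** (sodium, age at diagnosis, ICU days, therapy
  years) are truncated normals — sodium to 100–150 mEq/L, durations to
  positive values.  The location parameter is re-centred so the
  *post-truncation* mean equals the stated cohort mean; SDs are
  back-derived from the printed 95% CIs as
  `half_width * sqrt(n) / qt(0.975, n - 1)`.  The distributional shape is
  an assumption: only means and CIs are reported.
* **Reproducibility**: one integer seed drives named per-variable
  sub-streams, so adding a variable to the generator does not perturb
  the draws of existing ones, and identical truths give byte-identical
  cohorts.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: correlations among continuous
variables (sodium vs ICU stay, for instance) are unreported and generated
independently; birth group is drawn independently of clinical form, so
the secular trend in SW frequency (43% → 62% → 70% across birth eras)
that drives the mortality-deficit estimator is flattened to the
cohort-wide average; and no 17-OHP analyte values or birth-weight-specific
cutoffs are simulated — the cascade operates on rates, not assay levels.

## Statistical conventions in the estimators

* Means carry t-distribution 95% CIs; proportions carry Wilson score
  intervals (the source does not state its CI method).
* Two-group comparisons use Welch's unequal-variance t-test for means
  (the source says only "Student's t-test") and the uncorrected Pearson
  chi-square for proportions, switching the p-value to Fisher's exact
  test when any expected cell is below 5; the chi-square statistic is
  reported either way.
* "Recognized early" is operationalized as *diagnosed before the
  salt-wasting crisis* for SW and *diagnosed within 30 days of life* for
  SV.
* The mortality estimator is the SW-frequency deficit: the screened SW
  fraction (75%) minus the unscreened recent-cohort SW fraction, floored
  at zero.
* Statistics on empty subsets are reported as unavailable, never as
  zero.

## Test design and problem sizes

The unit suite freezes every published count and cent as expectations
and re-derives the non-tabulated oracles independently (closed-form 2x2
chi-square, year-by-year present-value summation, an expectation-based
continuous-mode evaluation of both arms with a propagated ±0.5-per-node
rounding bound).  Stochastic properties run at sizes chosen to finish in
seconds while keeping Monte-Carlo error far below the tolerances tested:
cascade conservation on 200 random cohorts, generator recovery on a
20-seed battery at n = 10,000 per form, and comparison-test calibration
on 200 null replicates checked against uniformity by Kolmogorov–Smirnov.
For the recovery battery, per-seed checks use a 4-SE gross-error bound
(the battery makes ~160 binomial checks, so a hard 3-SE bound per check
would false-alarm on roughly a third of seed batteries); the substantive
3-SE recovery assertion is made on the battery-pooled estimates, where
the Monte-Carlo error is √20 smaller.

## Known limitations

* The model has no false negatives: screening detects every affected
  newborn, and the very-low-birth-weight/transfusion recall stream is out
  of scope.
* Effects are deaths averted only; the screened arm's morbidity reduction
  enters through costs, not through the effect measure (no QALYs/DALYs).
* All sensitivity analysis is deterministic; no probabilistic (Monte
  Carlo over parameter distributions) analysis is provided.
* Indirect and family costs are excluded by the SUS perspective.
* Unit costs are SUS reimbursements, which likely understate true
  resource costs, particularly in the unscreened arm.
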