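#' @title Model parameters for the CAH newborn-screening decision model
#' @description
#' The decision model is driven by a single nested parameter object
#' (`cah_params`) with five blocks:
#'
#' * `epidemiology` — live births, CAH incidence (stored as the denominator of
#'   the 1:N rate to avoid decimal drift), salt-wasting (SW) fraction,
#'   clinical recognition probabilities, SW mortality without screening, life
#'   expectancy and the discounted life-years credited per death averted.
#' * `screening` — first-tier false-positive (FP) rate and the split of FPs
#'   into high-risk (serum confirmatory test) and low-risk (filter-paper
#'   retest) streams, with the residual FP fraction of each stream.
#' * `sw` — hospitalization/ICU rates and ICU length of stay for unrecognized
#'   SW cases, separately for the screened and unscreened strategies.
#' * `sv` — long-term therapy parameters for unrecognized simple-virilizing
#'   (SV) cases: growth hormone (GH), GnRH analog (GnRHa), and the
#'   masculinization pathway for 46,XX patients reared as males.
#' * `costs` — Brazilian public-health-system (SUS) unit reimbursements in
#'   2016 US$.
#'
#' @name cah-params
NULL

# Scenario columns: each preset differs from base only in the five fields
# the scenario table varies; everything else is shared.
.scenario_fields <- list(
  base  = list(cah_incidence_denominator = 12250, fp_rate = 0.002,
               clinical_recognition_sw = 0.36, clinical_recognition_sv = 0.28,
               sw_mortality_unscreened = 0.08),
  best  = list(cah_incidence_denominator = 10000, fp_rate = 0.001,
               clinical_recognition_sw = 0.16, clinical_recognition_sv = 0.11,
               sw_mortality_unscreened = 0.11),
  worst = list(cah_incidence_denominator = 15000, fp_rate = 0.005,
               clinical_recognition_sw = 0.55, clinical_recognition_sv = 0.45,
               sw_mortality_unscreened = 0.042),
  # Alternative input set derived from the most recent unscreened subcohort
  # (patients born 2000-2014): better clinical awareness, lower mortality.
  group3 = list(cah_incidence_denominator = 12250, fp_rate = 0.002,
                clinical_recognition_sw = 0.13, clinical_recognition_sv = 0.11,
                sw_mortality_unscreened = 0.05,
                hosp_rate_unscreened = 0.90, icu_rate_unscreened = 0.61,
                icu_days_unscreened = 20,
                gh_use_rate = 0.40, gh_years = 3.9, gh_dose_ui_per_day = 5.09,
                gnrha_use_rate = 0.30, gnrha_years = 5.1,
                masculinization_rate = 0.11)
)

.shared_params <- function() {
  list(
    epidemiology = list(
      live_births = 2923535,
      cah_incidence_denominator = NA_real_,
      sw_fraction = 0.75,
      clinical_recognition_sw = NA_real_,
      clinical_recognition_sv = NA_real_,
      sw_mortality_unscreened = NA_real_,
      life_expectancy_years = 76,
      discount_rate = 0.03,
      discounted_ly_per_death = 30.2
    ),
    screening = list(
      fp_rate = NA_real_,
      high_risk_fraction = 0.25,
      low_risk_fraction = 0.75,
      confirmatory_fp_fraction = 0.08,
      retest_fp_fraction = 0.005
    ),
    sw = list(
      hosp_rate_screened = 0.58,
      icu_rate_screened = 0.30,
      icu_days_screened = 9,
      hosp_rate_unscreened = 0.91,
      icu_rate_unscreened = 0.36,
      icu_days_unscreened = 23
    ),
    sv = list(
      gh_use_rate = 0.14,
      gh_years = 3.2,
      gh_dose_ui_per_day = 5.9,
      # 46,XX fraction of unrecognized SV feeding the masculinization node;
      # 0.5 (sex ratio at birth), exposed as an ordinary parameter.
      female_fraction = 0.5,
      masculinization_rate = 0.15,
      gnrha_use_rate = 0.28,
      gnrha_years = 3.8
    ),
    costs = list(
      ward_hospitalization = 70.8,
      icu_day = 155.9,
      screen_test_A = 2.45,
      confirm_consult_B = 22.46,
      gh_ampoule_price = 33.97,
      gh_ampoule_ui = 12,
      gnrha_ampoule_price = 273.75,
      masculinization = 1906.19,
      diagnostic_lab = 15.05
    )
  )
}

# block that owns each scalar field, for preset overrides and dotted paths
.block_of_field <- function(field, params) {
  for (blk in c("epidemiology", "screening", "sw", "sv", "costs")) {
    if (field %in% names(params[[blk]])) return(blk)
  }
  NULL
}

#' Preset parameter sets for the published scenarios
#'
#' Returns the complete parameter set for one of the named scenarios: the
#' `base`, `best` (assumptions favoring screening: higher incidence and
#' mortality, lower clinical recognition and FP rate) and `worst` columns of
#' the scenario table, plus `group3`, an alternative set built from the most
#' recent (born after 1999) unscreened subcohort.
#'
#' @param scenario one of `"base"`, `"best"`, `"worst"`, `"group3"`.
#' @return a validated `cah_params` object.
#' @examples
#' p <- cah_preset("base")
#' cah_incidence(p)   # 1/12250
#' @export
cah_preset <- function(scenario = c("base", "best", "worst", "group3")) {
  if (length(scenario) != 1 || !scenario %in% names(.scenario_fields)) {
    stop("unknown scenario '", paste(scenario, collapse = ","),
         "'; valid names: ", paste(names(.scenario_fields), collapse = ", "),
         call. = FALSE)
  }
  params <- .shared_params()
  for (field in names(.scenario_fields[[scenario]])) {
    blk <- .block_of_field(field, params)
    params[[blk]][[field]] <- .scenario_fields[[scenario]][[field]]
  }
  params$scenario_name <- scenario
  validate_params(new_cah_params(params))
}

new_cah_params <- function(x) structure(x, class = "cah_params")

#' @export
print.cah_params <- function(x, ...) {
  cat("<cah_params> scenario:", x$scenario_name, "\n")
  cat("  live births:", format(x$epidemiology$live_births, big.mark = ","),
      " incidence 1:", format(x$epidemiology$cah_incidence_denominator,
                              big.mark = ","), "\n", sep = "")
  cat("  SW fraction ", x$epidemiology$sw_fraction,
      ", recognition SW/SV ", x$epidemiology$clinical_recognition_sw, "/",
      x$epidemiology$clinical_recognition_sv,
      ", SW mortality ", x$epidemiology$sw_mortality_unscreened, "\n", sep = "")
  cat("  first-tier FP rate ", x$screening$fp_rate, "\n", sep = "")
  invisible(x)
}

#' CAH incidence as a probability per live birth
#'
#' @param params a `cah_params` object.
#' @return `1 / cah_incidence_denominator`.
#' @export
cah_incidence <- function(params) {
  1 / params$epidemiology$cah_incidence_denominator
}

.proportion_fields <- c(
  "epidemiology.sw_fraction", "epidemiology.clinical_recognition_sw",
  "epidemiology.clinical_recognition_sv",
  "epidemiology.sw_mortality_unscreened", "epidemiology.discount_rate",
  "screening.fp_rate", "screening.high_risk_fraction",
  "screening.low_risk_fraction", "screening.confirmatory_fp_fraction",
  "screening.retest_fp_fraction",
  "sw.hosp_rate_screened", "sw.icu_rate_screened",
  "sw.hosp_rate_unscreened", "sw.icu_rate_unscreened",
  "sv.gh_use_rate", "sv.female_fraction", "sv.masculinization_rate",
  "sv.gnrha_use_rate"
)

#' Validate a parameter object
#'
#' Checks every type invariant: proportions in \[0, 1\], non-negative counts,
#' durations and unit costs, a positive incidence denominator, and
#' `high_risk_fraction + low_risk_fraction == 1`.  Errors name the offending
#' field.
#'
#' @param params a `cah_params` object (or plain list with the same shape).
#' @return the validated object, invisibly classed as `cah_params`.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "cah_params")) params <- new_cah_params(params)
  for (blk in c("epidemiology", "screening", "sw", "sv", "costs")) {
    if (is.null(params[[blk]])) fail_field(blk, "block missing")
  }
  for (path in .proportion_fields) {
    v <- param_get(params, path)
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      fail_field(path, sprintf("proportion must lie in [0, 1], got %s",
                               format(v)))
  }
  epi <- params$epidemiology
  if (is.na(epi$live_births) || epi$live_births < 0 ||
      epi$live_births != round_half_up(epi$live_births))
    fail_field("epidemiology.live_births", "must be a non-negative integer")
  if (is.na(epi$cah_incidence_denominator) ||
      epi$cah_incidence_denominator <= 0)
    fail_field("epidemiology.cah_incidence_denominator", "must be positive")
  if (is.na(epi$discounted_ly_per_death) || epi$discounted_ly_per_death <= 0)
    fail_field("epidemiology.discounted_ly_per_death", "must be positive")
  if (is.na(epi$life_expectancy_years) || epi$life_expectancy_years <= 0)
    fail_field("epidemiology.life_expectancy_years", "must be positive")
  scr <- params$screening
  if (abs(scr$high_risk_fraction + scr$low_risk_fraction - 1) > 1e-9)
    fail_field("screening.high_risk_fraction",
               "high_risk_fraction + low_risk_fraction must equal 1")
  for (f in c("icu_days_screened", "icu_days_unscreened")) {
    if (is.na(params$sw[[f]]) || params$sw[[f]] < 0)
      fail_field(paste0("sw.", f), "must be >= 0")
  }
  for (f in c("gh_years", "gh_dose_ui_per_day", "gnrha_years")) {
    if (is.na(params$sv[[f]]) || params$sv[[f]] < 0)
      fail_field(paste0("sv.", f), "must be >= 0")
  }
  for (f in names(params$costs)) {
    if (is.na(params$costs[[f]]) || params$costs[[f]] < 0)
      fail_field(paste0("costs.", f), "unit cost must be >= 0")
  }
  invisible(params)
}

#' Get or set one scalar parameter by dotted path
#'
#' Paths are `"block.field"`, e.g. `"epidemiology.sw_mortality_unscreened"`.
#'
#' @param params a `cah_params` object.
#' @param path character scalar dotted path.
#' @param value replacement value (for `param_set`).
#' @return `param_get`: the scalar value; `param_set`: a modified copy of
#'   `params` (not revalidated, so sweeps may pass transient values; call
#'   [validate_params()] when the final object must satisfy all invariants).
#' @export
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(params[[parts[1]]]) ||
      !parts[2] %in% names(params[[parts[1]]]))
    stop("unresolvable parameter path '", path, "'", call. = FALSE)
  params[[parts[1]]][[parts[2]]]
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(params[[parts[1]]]) ||
      !parts[2] %in% names(params[[parts[1]]]))
    stop("unresolvable parameter path '", path, "'", call. = FALSE)
  params[[parts[1]]][[parts[2]]] <- value
  params
}

#' A one-way sensitivity range for one (or several paired) parameters
#'
#' A range holds the low and high plausible values of a scalar parameter.
#' Several paths may be given to move parameters jointly (the published
#' sensitivity analysis varies SW and SV clinical recognition together).
#'
#' @param parameter_path character vector of dotted paths.
#' @param low,high numeric vectors, same length as `parameter_path`, with
#'   `low <= high` elementwise.
#' @return a `param_range` object.
#' @export
param_range <- function(parameter_path, low, high) {
  stopifnot(length(low) == length(parameter_path),
            length(high) == length(parameter_path))
  if (any(low > high)) stop("range must satisfy low <= high", call. = FALSE)
  structure(list(parameter_path = parameter_path, low = low, high = high),
            class = "param_range")
}

#' Apply one end of a sensitivity range to a parameter set
#'
#' @param params a `cah_params` object.
#' @param range a [param_range()].
#' @param which `"low"` or `"high"`.
#' @return a copy of `params` with the range's parameter(s) replaced.
#' @export
apply_range <- function(params, range, which = c("low", "high")) {
  which <- match.arg(which)
  values <- range[[which]]
  for (i in seq_along(range$parameter_path)) {
    params <- param_set(params, range$parameter_path[i], values[i])
  }
  params
}

#' The published one-way sensitivity ranges
#'
#' The four ranges of the deterministic sensitivity analysis: CAH incidence
#' 1:15,000 to 1:10,000, joint SW/SV clinical recognition 16/11% to 55/45%,
#' SW mortality without screening 4.2% to 11%, and first-tier FP rate 0.1%
#' to 0.5%.
#'
#' @return named list of [param_range()] objects.
#' @export
table_ranges <- function() {
  list(
    incidence = param_range("epidemiology.cah_incidence_denominator",
                            low = 10000, high = 15000),
    recognition = param_range(
      c("epidemiology.clinical_recognition_sw",
        "epidemiology.clinical_recognition_sv"),
      low = c(0.16, 0.11), high = c(0.55, 0.45)),
    sw_mortality = param_range("epidemiology.sw_mortality_unscreened",
                               low = 0.042, high = 0.11),
    fp_rate = param_range("screening.fp_rate", low = 0.001, high = 0.005)
  )
}

#' Load model parameters from a YAML configuration
#'
#' The document may name a preset via a top-level `scenario:` key (default
#' `"base"`); any field in the five parameter blocks can then be overridden.
#' Unknown keys are reported with a warning; invariant violations are errors
#' naming the field.
#'
#' @param file path to a YAML file, or `NULL` when `text` is given.
#' @param text YAML document as a string (alternative to `file`).
#' @return a validated `cah_params` object.
#' @examples
#' p <- load_params(text = "scenario: base\nscreening:\n  fp_rate: 0.005\n")
#' p$screening$fp_rate  # 0.005
#' @export
load_params <- function(file = NULL, text = NULL) {
  doc <- if (is.null(text)) yaml::read_yaml(file) else
    yaml::yaml.load(text)
  if (!is.list(doc)) stop("configuration must be a YAML mapping",
                          call. = FALSE)
  scenario <- doc$scenario %||% "base"
  params <- cah_preset(scenario)
  blocks <- c("epidemiology", "screening", "sw", "sv", "costs")
  unknown <- setdiff(names(doc), c("scenario", "scenario_name", blocks))
  if (length(unknown))
    warning("ignoring unknown configuration keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  for (blk in intersect(names(doc), blocks)) {
    bad <- setdiff(names(doc[[blk]]), names(params[[blk]]))
    if (length(bad))
      warning("ignoring unknown keys in '", blk, "': ",
              paste(bad, collapse = ", "), call. = FALSE)
    for (field in intersect(names(doc[[blk]]), names(params[[blk]]))) {
      params[[blk]][[field]] <- doc[[blk]][[field]]
    }
  }
  if (!is.null(doc$scenario_name)) params$scenario_name <- doc$scenario_name
  validate_params(params)
}

#' Serialize model parameters to YAML
#'
#' Round-trips with [load_params()]: the emitted document reloads to an
#' identical parameter object.
#'
#' @param params a `cah_params` object.
#' @param file optional path; when `NULL` the YAML text is returned.
#' @return YAML text (invisibly when written to `file`).
#' @export
serialize_params <- function(params, file = NULL) {
  doc <- unclass(params)
  doc <- c(list(scenario = params$scenario_name %||% "base"),
           doc[c("epidemiology", "screening", "sw", "sv", "costs")])
  txt <- yaml::as.yaml(doc, precision = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
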