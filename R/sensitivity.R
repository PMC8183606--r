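#' One-way deterministic sensitivity sweep
#'
#' Re-runs the full integer-rounded decision model at `n_points` values
#' spaced linearly between each range's low and high end (inclusive), all
#' other parameters held at `base`.  Paired ranges (several paths) move
#' their parameters jointly along the same grid.
#'
#' @param base a `cah_params` object, the anchor parameter set.
#' @param ranges list of [param_range()] objects (optionally named).
#' @param n_points number of evaluation points per range, >= 2.
#' @return data frame with one row per evaluation: `parameter_path` (paths
#'   joined by `+` for paired ranges), `tested_value` (value of the first
#'   path), `icer`, `deaths_averted`, `incremental_cost`.
#' @examples
#' sweep <- one_way_sweep(cah_preset("base"),
#'                        table_ranges()["sw_mortality"], n_points = 2)
#' @export
one_way_sweep <- function(base, ranges, n_points = 2) {
  stopifnot(n_points >= 2)
  rows <- lapply(ranges, function(rg) {
    frac <- seq(0, 1, length.out = n_points)
    evals <- lapply(frac, function(f) {
      p <- base
      for (i in seq_along(rg$parameter_path)) {
        p <- param_set(p, rg$parameter_path[i],
                       rg$low[i] + f * (rg$high[i] - rg$low[i]))
      }
      res <- run_cea(p)$result
      data.frame(
        parameter_path = paste(rg$parameter_path, collapse = "+"),
        tested_value = rg$low[1] + f * (rg$high[1] - rg$low[1]),
        icer = res$icer,
        deaths_averted = res$deaths_averted,
        incremental_cost = res$incremental_cost,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, evals)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare named parameter scenarios
#'
#' Evaluates the full CEA once per scenario and tabulates the headline
#' results.
#'
#' @param scenarios list of `cah_params` objects (names taken from the list
#'   names or each scenario's `scenario_name`).
#' @return data frame with one row per scenario: `scenario`,
#'   `screened_cost`, `unscreened_cost`, `incremental_cost`,
#'   `deaths_averted`, `cost_per_death_averted`, `icer`.
#' @examples
#' scenario_comparison(list(cah_preset("base"), cah_preset("best")))
#' @export
scenario_comparison <- function(scenarios) {
  stopifnot(length(scenarios) >= 1)
  labels <- names(scenarios)
  rows <- lapply(seq_along(scenarios), function(i) {
    cea <- run_cea(scenarios[[i]])
    label <- if (!is.null(labels) && nzchar(labels[i])) labels[i] else
      scenarios[[i]]$scenario_name %||% paste0("scenario_", i)
    data.frame(
      scenario = label,
      screened_cost = cea$screened$total_cost,
      unscreened_cost = cea$unscreened$total_cost,
      incremental_cost = cea$result$incremental_cost,
      deaths_averted = cea$result$deaths_averted,
      cost_per_death_averted = cea$result$cost_per_death_averted,
      icer = cea$result$icer,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tornado table of one-way sensitivity ranges
#'
#' Evaluates the ICER at both endpoints of every range and orders the
#' parameters by the span `|icer_high - icer_low|`, descending — the
#' conventional tornado-diagram ordering identifying the most influential
#' parameters.  Ties break lexically on `parameter_path`, so the ordering
#' does not depend on the input list order.
#'
#' @param base a `cah_params` object.
#' @param ranges list of [param_range()] objects.
#' @return data frame `parameter_path`, `icer_at_low`, `icer_at_high`,
#'   `span`, sorted by descending span.
#' @export
tornado <- function(base, ranges) {
  rows <- lapply(ranges, function(rg) {
    lo <- run_cea(apply_range(base, rg, "low"))$result$icer
    hi <- run_cea(apply_range(base, rg, "high"))$result$icer
    data.frame(
      parameter_path = paste(rg$parameter_path, collapse = "+"),
      icer_at_low = lo, icer_at_high = hi,
      span = abs(hi - lo),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter_path), ]
  rownames(out) <- NULL
  out
}
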