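#' Round half away from zero
#'
#' Commercial rounding as used throughout the decision model: .5 always moves
#' away from zero, unlike [base::round()] which rounds half to even.  Applied
#' at every "rate x count" node of the tree so that the integer cohort counts
#' are reproducible.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (0 for whole counts, 2 for
#'   currency).
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(179.25)      # 179
#' round_half_up(0.5)         # 1, where round(0.5) gives 0
#' round_half_up(24.905, 2)   # 24.91
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # 1e-9 guard: products such as 43 * 0.075 sit a few ulp below the exact
  # decimal value; without it a true .5 boundary could round down.
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Round a monetary amount to whole cents
#'
#' @param x numeric, US$ amounts.
#' @return numeric rounded to 2 decimals, half away from zero.
#' @export
round_cents <- function(x) round_half_up(x, 2)

# stop() with the offending field named, for validator messages
fail_field <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}
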