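#' Population-level policy cost projection
#'
#' The back-of-the-envelope arithmetic for the annual hospital-cost
#' consequence of a population-wide exposure shift:
#' `total_cost = population * delta_exposure * beta`, carried at full
#' floating-point precision.
#'
#' @param population Number of adults (non-negative).
#' @param delta_exposure Exposure shift in natural units (kg/m\eqn{^2}).
#' @param beta Causal effect in pounds per unit per person-year.
#' @return A one-row tibble of class `policy_projection` with the inputs and
#'   `total_cost` (pounds per year).
#' @export
#' @examples
#' policy_cost_projection(50e6, 1, 18.85)$total_cost  # 942,500,000
policy_cost_projection <- function(population, delta_exposure, beta) {
  if (!all(is.finite(c(population, delta_exposure, beta)))) {
    abort("all inputs must be finite.", class = "mrcost_error_arg")
  }
  if (population < 0) {
    abort("`population` must be non-negative.", class = "mrcost_error_arg")
  }
  out <- tibble(population = population,
                delta_exposure = delta_exposure,
                beta = beta,
                total_cost = population * delta_exposure * beta)
  class(out) <- c("policy_projection", class(tibble()))
  out
}

#' Difference between two policy projections
#'
#' @param projection1,projection2 `policy_projection` tibbles.
#' @return The difference in total annual cost (pounds), `projection1` minus
#'   `projection2`.
#' @export
#' @examples
#' policy_cost_difference(
#'   policy_cost_projection(50e6, 1, 18.85),
#'   policy_cost_projection(50e6, 1, 13.47)
#' )  # 269,000,000
policy_cost_difference <- function(projection1, projection2) {
  projection1$total_cost - projection2$total_cost
}

#' Convert US dollars to pounds sterling
#'
#' Divides a dollar amount by the dollars-per-pound exchange rate. Full
#' precision is retained; round only for display.
#'
#' @param amount_usd Amount in US dollars.
#' @param usd_per_gbp Dollars per pound (must be positive).
#' @return Amount in pounds, full precision.
#' @export
#' @examples
#' round(currency_convert(54, 1.82), 2)  # 29.67
currency_convert <- function(amount_usd, usd_per_gbp) {
  if (!is.finite(usd_per_gbp) || usd_per_gbp <= 0) {
    abort("`usd_per_gbp` must be positive.", class = "mrcost_error_arg")
  }
  amount_usd / usd_per_gbp
}
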