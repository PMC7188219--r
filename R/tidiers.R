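#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`exposure`, and
#'   `(intercept)` for methods that estimate average pleiotropy), with
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble(
    method = x$method, term = "exposure",
    estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pval
  )
  if (!is.na(x$intercept)) {
    out <- dplyr::bind_rows(out, tibble(
      method = x$method, term = "(intercept)",
      estimate = x$intercept, std.error = x$intercept_se,
      statistic = x$intercept / x$intercept_se, p.value = x$intercept_pval
    ))
  }
  out
}

#' One-row summary of an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, its heterogeneity statistics
#'   and the number of instruments.
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, beta = x$beta, se = x$se, pval = x$pval,
         n_snps = x$n_snps, q = x$q, q_df = x$q_df, q_pval = x$q_pval,
         converged = x$converged)
}

#' @method tidy family_iv
#' @export
tidy.family_iv <- function(x, ...) {
  tibble(term = "exposure", estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$pval)
}

#' @method glance family_iv
#' @export
glance.family_iv <- function(x, ...) {
  tibble(beta = x$beta, se = x$se, pval = x$pval,
         n_individuals = x$n_individuals, n_families = x$n_families,
         used_fixed_effects = x$used_fixed_effects)
}

#' @method tidy mr_nonlinear
#' @export
tidy.mr_nonlinear <- function(x, ...) {
  tibble(
    test = c("fracpoly_d1_vs_linear", "fracpoly_d2_vs_d1",
             "quadratic", "trend", "first_stage_heterogeneity"),
    p.value = c(x$fracpoly_d1_vs_linear_pval, x$fracpoly_d2_vs_d1_pval,
                x$quadratic_pval, x$trend_pval,
                x$first_stage_heterogeneity_pval)
  )
}

#' @method glance mr_nonlinear
#' @export
glance.mr_nonlinear <- function(x, ...) {
  tibble(n_strata = nrow(x$strata),
         best_power_d1 = x$best_power_d1,
         trend_slope = x$trend_slope,
         trend_slope_se = x$trend_slope_se)
}
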