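#' Residual exposure with respect to the allele score
#'
#' The difference between the exposure and the fitted values from a
#' regression of the exposure on the weighted allele score: the part of the
#' exposure not predicted by genotype. Stratifying on this residual (rather
#' than on the raw exposure, which is a downstream consequence of the
#' instrument) preserves the exclusion restriction when probing
#' non-linearity.
#'
#' @param cohort A cohort tibble.
#' @param score Allele-score vector.
#' @return Numeric residual vector, orthogonal to the score by construction.
#' @export
residualize_exposure <- function(cohort, score) {
  if (sd(score) == 0) abort("score is constant.", class = "mrcost_error_arg")
  x <- cohort$exposure
  sl <- simple_slope(x, score)
  x - (mean(x) + sl$beta * (score - mean(score)))
}

#' Quantile-stratified local average causal effects (LACE)
#'
#' Ranks individuals into `K` equal-size strata of residual exposure and, in
#' each stratum, divides the stratum-specific score-to-cost association by
#' the whole-sample score-to-exposure association. Each quotient is the
#' local average causal effect (pounds per exposure unit) in that part of
#' the exposure distribution; its standard error applies the delta method to
#' the numerator, treating the (whole-sample, much more precise) denominator
#' as fixed. Per-stratum first-stage estimates are retained so the constancy
#' of the instrument-exposure association can be tested.
#'
#' @param cohort A cohort tibble.
#' @param score Allele-score vector.
#' @param residual Residual exposure from [residualize_exposure()]; computed
#'   if omitted.
#' @param K Number of quantile strata (default 100). Requires `n >= 10 K`.
#' @return A tibble of class `mr_lace`: `stratum`, `mean_exposure`, `lace`,
#'   `se`, `n_stratum`, `fs_beta`, `fs_se`, with the whole-sample first
#'   stage as attributes `first_stage`/`first_stage_se`.
#' @export
stratify_lace <- function(cohort, score, residual = NULL, K = 100) {
  n <- nrow(cohort)
  if (n < 10 * K) {
    abort(sprintf("n = %d is too small for K = %d strata (need n >= 10K); use a smaller K.",
                  n, K), class = "mrcost_error_arg")
  }
  if (is.null(residual)) residual <- residualize_exposure(cohort, score)
  fs <- simple_slope(cohort$exposure, score)

  # stable ranking: residual, then row order
  ord <- order(residual)
  sizes <- rep(n %/% K, K)
  if (n %% K) sizes[seq_len(n %% K)] <- sizes[seq_len(n %% K)] + 1L
  stratum <- integer(n)
  stratum[ord] <- rep(seq_len(K), times = sizes)

  res <- purrr::map_dfr(seq_len(K), function(k) {
    idx <- stratum == k
    rf <- simple_slope(cohort$cost[idx], score[idx])
    fk <- simple_slope(cohort$exposure[idx], score[idx])
    tibble(
      stratum = k,
      mean_exposure = mean(cohort$exposure[idx]),
      lace = rf$beta / fs$beta,
      se = rf$se / abs(fs$beta),
      n_stratum = sum(idx),
      fs_beta = fk$beta,
      fs_se = fk$se
    )
  })
  structure(res, class = c("mr_lace", class(tibble())),
            first_stage = fs$beta, first_stage_se = fs$se)
}

# fractional-polynomial basis for one or two powers (0 means log; repeated
# powers use the Royston-Altman log-multiplied second term)
fp_basis <- function(x, powers) {
  tp <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1L) {
    cbind(tp(powers))
  } else if (powers[1] == powers[2]) {
    b <- tp(powers[1])
    cbind(b, b * log(x))
  } else {
    cbind(tp(powers[1]), tp(powers[2]))
  }
}

#' Tests of non-linearity of the causal effect
#'
#' Inverse-variance-weighted meta-regression of the stratum LACE estimates on
#' transformed stratum mean exposure, with the LACE standard errors treated
#' as known:
#' \itemize{
#'   \item fractional polynomial of degree 1 (best power from
#'     \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, 0 = log) against the linear model
#'     (likelihood-ratio chi-square, 1 df);
#'   \item fractional polynomial of degree 2 (all power pairs) against the
#'     best degree-1 model (2 df);
#'   \item quadratic test: z-test of the squared term in a quadratic
#'     meta-regression;
#'   \item trend test: z-test of the slope in a linear weighted
#'     meta-regression of LACE on mean exposure;
#'   \item heterogeneity of the per-stratum first-stage (instrument to
#'     exposure) associations, chi-square with K-1 df.
#' }
#' A flat LACE profile (constant causal effect) leaves all four tests null.
#'
#' @param strata An `mr_lace` tibble from [stratify_lace()].
#' @return A list of class `mr_nonlinear` with the five p-values, the best
#'   fractional-polynomial powers, and the input strata.
#' @export
nonlinearity_tests <- function(strata) {
  ok <- is.finite(strata$lace) & is.finite(strata$se) & strata$se > 0
  s <- strata[ok, ]
  if (nrow(s) < 10L) {
    abort("need at least 10 strata with finite standard errors.",
          class = "mrcost_error_arg")
  }
  if (any(s$mean_exposure <= 0)) {
    abort("fractional powers require strictly positive mean exposures.",
          class = "mrcost_error_arg")
  }
  y <- s$lace
  x <- s$mean_exposure
  w <- 1 / s$se^2

  # centre and rescale basis columns for conditioning; the weighted residual
  # sum (deviance) and z statistics are invariant to this
  dev_of <- function(B) wls_known_var(cbind(1, scale(B)), y, w)$rss
  powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

  dev_lin <- dev_of(cbind(x))
  d1 <- vapply(powers, function(p) dev_of(fp_basis(x, p)), numeric(1))
  best_p1 <- powers[which.min(d1)]
  dev_d1 <- min(d1)

  pairs <- expand.grid(p1 = powers, p2 = powers)
  pairs <- pairs[pairs$p1 <= pairs$p2, ]
  d2 <- mapply(function(p1, p2) dev_of(fp_basis(x, c(p1, p2))),
               pairs$p1, pairs$p2)
  best_p2 <- unlist(pairs[which.min(d2), ])
  dev_d2 <- min(d2)

  fp1_p <- pchisq(max(0, dev_lin - dev_d1), df = 1, lower.tail = FALSE)
  fp2_p <- pchisq(max(0, dev_d1 - dev_d2), df = 2, lower.tail = FALSE)

  quad <- wls_known_var(cbind(1, x, x^2), y, w)
  quad_p <- unname(two_sided_p(quad$beta[3] / quad$se[3]))

  trend <- wls_known_var(cbind(1, x), y, w)
  trend_p <- unname(two_sided_p(trend$beta[2] / trend$se[2]))

  wf <- 1 / s$fs_se^2
  fs_bar <- sum(wf * s$fs_beta) / sum(wf)
  q_fs <- sum(wf * (s$fs_beta - fs_bar)^2)
  fs_p <- pchisq(q_fs, df = nrow(s) - 1L, lower.tail = FALSE)

  structure(list(
    strata = strata,
    fracpoly_d1_vs_linear_pval = fp1_p,
    fracpoly_d2_vs_d1_pval = fp2_p,
    quadratic_pval = quad_p,
    trend_pval = trend_p,
    first_stage_heterogeneity_pval = fs_p,
    best_power_d1 = best_p1,
    best_powers_d2 = unname(best_p2),
    trend_slope = unname(trend$beta[2]),
    trend_slope_se = unname(trend$se[2])
  ), class = "mr_nonlinear")
}

#' @export
print.mr_nonlinear <- function(x, ...) {
  cat("Non-linearity tests on", nrow(x$strata), "strata\n")
  cat(sprintf("  fractional polynomial d1 vs linear: p = %.3g (best power %g)\n",
              x$fracpoly_d1_vs_linear_pval, x$best_power_d1))
  cat(sprintf("  fractional polynomial d2 vs d1:     p = %.3g (powers %g, %g)\n",
              x$fracpoly_d2_vs_d1_pval,
              x$best_powers_d2[1], x$best_powers_d2[2]))
  cat(sprintf("  quadratic term:                     p = %.3g\n", x$quadratic_pval))
  cat(sprintf("  trend (LACE on mean exposure):      p = %.3g\n", x$trend_pval))
  cat(sprintf("  first-stage heterogeneity:          p = %.3g\n",
              x$first_stage_heterogeneity_pval))
  invisible(x)
}
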