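new_mr_estimate <- function(method, beta, se, n_snps,
                            q = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_pval = NA_real_, converged = TRUE,
                            extra = list()) {
  stopifnot(is.finite(beta))
  structure(c(list(
    method = method,
    beta = beta,
    se = se,
    pval = two_sided_p(beta / se),
    n_snps = n_snps,
    q = q, q_df = q_df, q_pval = q_pval,
    intercept = intercept, intercept_se = intercept_se,
    intercept_pval = intercept_pval,
    converged = converged
  ), extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.3f (se %.3f, p = %.3g), %d SNPs\n",
              x$method, x$beta, x$se, x$pval, x$n_snps))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept = %.3f (se %.3f, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.2f (df %d, p = %.3g)\n",
                x$q, as.integer(x$q_df), x$q_pval))
  }
  invisible(x)
}

# pull the harmonized (gamma_hat, se_x, Gamma_hat, se_y) columns
summary_cols <- function(summaries, min_snps = 1L, method = "estimator") {
  s <- kept_summaries(summaries)
  if (nrow(s) < min_snps) {
    abort(sprintf("%s requires at least %d SNPs (got %d).",
                  method, min_snps, nrow(s)),
          class = "mrcost_error_few_snps")
  }
  list(snp = s$snp,
       be = s$beta_exposure, sx = s$se_exposure,
       bo = s$beta_outcome, sy = s$se_outcome,
       J = nrow(s))
}

#' Per-SNP Wald (ratio) estimates
#'
#' The single-instrument IV estimate for each SNP: the SNP-outcome
#' association divided by the SNP-exposure association. The first-order
#' standard error \eqn{\sigma_Y / |\hat\gamma|} ignores the exposure-side
#' sampling error (the no-measurement-error, NOME, assumption); a
#' second-order delta-method correction is available behind
#' `second_order = TRUE`.
#'
#' @param summaries An `mr_summaries` tibble.
#' @param second_order Include the exposure-side variance term in the ratio
#'   standard error.
#' @return A tibble with `snp`, `ratio` (pounds per exposure unit),
#'   `se_ratio`, `weight` (= `se_ratio^-2`).
#' @export
wald_ratios <- function(summaries, second_order = FALSE) {
  sc <- summary_cols(summaries, 1L, "wald_ratios")
  if (any(sc$be == 0)) {
    abort("undefined ratio: SNP-exposure association is zero.",
          class = "mrcost_error_zero_gamma")
  }
  se2 <- sc$sy^2 / sc$be^2
  if (second_order) se2 <- se2 + sc$bo^2 * sc$sx^2 / sc$be^4
  tibble(snp = sc$snp,
         ratio = sc$bo / sc$be,
         se_ratio = sqrt(se2),
         weight = 1 / se2)
}

#' Inverse-variance-weighted MR estimate
#'
#' Combines the per-SNP ratio estimates by inverse-variance weighting,
#' \deqn{\hat\beta_{IVW} = \frac{\sum_j \hat\gamma_j^2 \sigma_{Yj}^{-2}
#'   \hat\beta_j}{\sum_j \hat\gamma_j^2 \sigma_{Yj}^{-2}},}
#' equivalent to a zero-intercept weighted regression of the outcome
#' associations on the exposure associations with weights
#' \eqn{\sigma_{Yj}^{-2}}. Under multiplicative random effects the standard
#' error is inflated by \eqn{\sqrt{\max(1, Q/(J-1))}} and never shrinks below
#' the fixed-effects value.
#'
#' @param summaries An `mr_summaries` tibble.
#' @param effects `"random"` (multiplicative, the default) or `"fixed"`.
#' @return An object of class `mr_estimate` with Cochran's Q attached.
#' @export
mr_ivw <- function(summaries, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  sc <- summary_cols(summaries, 1L, "mr_ivw")
  if (all(sc$be == 0)) {
    abort("all SNP-exposure associations are zero.",
          class = "mrcost_error_zero_gamma")
  }
  w <- 1 / sc$sy^2
  denom <- sum(w * sc$be^2)
  beta <- sum(w * sc$be * sc$bo) / denom
  se_fixed <- sqrt(1 / denom)
  q <- sum(w * (sc$bo - beta * sc$be)^2)
  q_df <- sc$J - 1L
  q_pval <- if (q_df >= 1) pchisq(q, q_df, lower.tail = FALSE) else NA_real_
  se <- if (effects == "random" && q_df >= 1) {
    se_fixed * sqrt(max(1, q / q_df))
  } else {
    se_fixed
  }
  label <- if (effects == "random") "IVW (multiplicative random effects)"
           else "IVW (fixed effects)"
  new_mr_estimate(label, beta, se, sc$J,
                  q = q, q_df = q_df, q_pval = q_pval,
                  extra = list(se_fixed = se_fixed, effects = effects))
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (\hat\beta_j - \beta_{ref})^2} with
#' \eqn{w_j = \hat\gamma_j^2 \sigma_{Yj}^{-2}}; under valid instruments Q
#' follows a chi-square distribution with \eqn{J - 1} degrees of freedom.
#'
#' @param summaries An `mr_summaries` tibble (at least 2 SNPs).
#' @param beta_ref Reference causal estimate (defaults to the IVW estimate).
#' @return A one-row tibble with `q`, `df`, `pval`, and the per-SNP
#'   contributions as attribute `"contributions"`.
#' @export
mr_cochran_q <- function(summaries, beta_ref = NULL) {
  sc <- summary_cols(summaries, 2L, "mr_cochran_q")
  if (is.null(beta_ref)) beta_ref <- mr_ivw(summaries, "fixed")$beta
  contrib <- ((sc$bo - beta_ref * sc$be) / sc$sy)^2
  q <- sum(contrib)
  df <- sc$J - 1L
  out <- tibble(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
  attr(out, "contributions") <- setNames(contrib, sc$snp)
  out
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome associations on the exposure
#' associations with an unconstrained intercept (weights
#' \eqn{\sigma_{Yj}^{-2}}). The slope estimates the causal effect under the
#' InSIDE condition (instrument strength independent of direct effects); the
#' intercept estimates the average directional pleiotropic effect, and its
#' test against zero is a pleiotropy diagnostic. Exposure associations are
#' re-oriented to be positive before fitting. Standard errors use the
#' multiplicative random-effects inflation \eqn{\sqrt{\max(1, Q/(J-2))}}.
#'
#' @param summaries An `mr_summaries` tibble (at least 3 SNPs).
#' @return An `mr_estimate` with intercept fields and Egger's Q (df J-2).
#' @export
mr_egger <- function(summaries) {
  sc <- summary_cols(summaries, 3L, "mr_egger")
  flip <- sign(sc$be)
  flip[flip == 0] <- 1
  be <- sc$be * flip
  bo <- sc$bo * flip
  w <- 1 / sc$sy^2
  fit <- wls_known_var(cbind(1, be), bo, w)
  fit$beta <- unname(fit$beta)
  q <- fit$rss
  q_df <- sc$J - 2L
  q_pval <- pchisq(q, q_df, lower.tail = FALSE)
  infl <- sqrt(max(1, q / q_df))
  se <- fit$se * infl
  new_mr_estimate("MR-Egger", fit$beta[2], se[2], sc$J,
                  q = q, q_df = q_df, q_pval = q_pval,
                  intercept = fit$beta[1], intercept_se = se[1],
                  intercept_pval = two_sided_p(fit$beta[1] / se[1]))
}

# weighted median of ratio estimates with linear interpolation in cumulative
# standardized weight; ties broken by snp order (stable sort)
weighted_median_ <- function(ratio, w, snp = seq_along(ratio)) {
  ord <- order(ratio, snp)
  r <- ratio[ord]
  ws <- w[ord]
  cum <- (cumsum(ws) - ws / 2) / sum(ws)
  if (0.5 <= cum[1]) return(r[1])
  J <- length(r)
  if (0.5 >= cum[J]) return(r[J])
  i <- findInterval(0.5, cum)
  r[i] + (r[i + 1] - r[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

pwm_point <- function(be, bo, sy, snp, penalized, penalty) {
  ratio <- bo / be
  w <- be^2 / sy^2
  est <- weighted_median_(ratio, w, snp)
  if (penalized) {
    qj <- w * (ratio - est)^2
    pj <- pchisq(qj, 1, lower.tail = FALSE)
    est <- weighted_median_(ratio, w * pmin(1, penalty * pj), snp)
  }
  est
}

#' Penalized weighted median MR estimate
#'
#' The causal estimate at the 50\% point of cumulative standardized
#' inverse-variance weight across the ordered per-SNP ratio estimates,
#' consistent when more than half of the weight comes from valid
#' instruments. Penalization down-weights outlying SNPs by their
#' contribution to heterogeneity: each weight is multiplied by
#' \eqn{\min(1, 20 p_j)} where \eqn{p_j} is the upper-tail \eqn{\chi^2_1}
#' probability of SNP j's Q contribution at the unpenalized weighted-median
#' estimate. The standard error comes from a parametric bootstrap of the
#' summary pairs.
#'
#' @param summaries An `mr_summaries` tibble (at least 3 SNPs).
#' @param penalized Apply the heterogeneity penalty (default `TRUE`).
#' @param penalty Penalization constant (default 20).
#' @param n_boot Bootstrap replicates (default 1000; fewer than 100 warns).
#' @param seed Optional seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(summaries, penalized = TRUE, penalty = 20,
                               n_boot = 1000, seed = NULL) {
  sc <- summary_cols(summaries, 3L, "mr_weighted_median")
  if (n_boot < 100) {
    warn("fewer than 100 bootstrap replicates; the standard error will be noisy.")
  }
  est <- pwm_point(sc$be, sc$bo, sc$sy, sc$snp, penalized, penalty)
  maybe_seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    be_b <- rnorm(sc$J, sc$be, sc$sx)
    bo_b <- rnorm(sc$J, sc$bo, sc$sy)
    pwm_point(be_b, bo_b, sc$sy, sc$snp, penalized, penalty)
  }, numeric(1))
  se <- sd(boots)
  label <- if (penalized) "Penalized weighted median" else "Weighted median"
  new_mr_estimate(label, est, se, sc$J, extra = list(n_boot = n_boot))
}

mode_point <- function(ratio, w, bandwidth_factor) {
  spread <- min(sd(ratio), mad(ratio))
  if (spread == 0) spread <- max(sd(ratio), mad(ratio))
  if (spread == 0) return(ratio[1])  # degenerate: all ratios identical
  h <- bandwidth_factor * 0.9 * spread * length(ratio)^(-1 / 5)
  d <- density(ratio, weights = w / sum(w), bw = h, n = 512,
               from = min(ratio) - 3 * h, to = max(ratio) + 3 * h)
  d$x[which.max(d$y)]
}

#' Weighted mode MR estimate
#'
#' The maximizer of a Gaussian-kernel-smoothed density of the per-SNP ratio
#' estimates, weighted by their inverse variances: consistent if the largest
#' homogeneous cluster of instruments is valid (zero modal pleiotropy), even
#' when a majority of SNPs are invalid. The bandwidth is
#' `bandwidth_factor` times the modified Silverman rule
#' \eqn{0.9 \min(sd, mad) J^{-1/5}} on the ratio set; the density is
#' evaluated on a 512-point grid spanning the ratios +/- 3 bandwidths. The
#' standard error comes from a parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth
#'   (default 1).
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(summaries, bandwidth_factor = 1,
                             n_boot = 1000, seed = NULL) {
  sc <- summary_cols(summaries, 3L, "mr_weighted_mode")
  if (n_boot < 100) {
    warn("fewer than 100 bootstrap replicates; the standard error will be noisy.")
  }
  ratio <- sc$bo / sc$be
  w <- sc$be^2 / sc$sy^2
  est <- mode_point(ratio, w, bandwidth_factor)
  maybe_seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    be_b <- rnorm(sc$J, sc$be, sc$sx)
    bo_b <- rnorm(sc$J, sc$bo, sc$sy)
    mode_point(bo_b / be_b, be_b^2 / sc$sy^2, bandwidth_factor)
  }, numeric(1))
  se <- sd(boots)
  new_mr_estimate("Weighted mode", est, se, sc$J,
                  extra = list(bandwidth_factor = bandwidth_factor,
                               n_boot = n_boot))
}

#' Robust adjusted profile score (RAPS) MR estimate
#'
#' Maximizes the profile log-likelihood
#' \deqn{\ell(\beta) = -\tfrac12 \sum_j \frac{(\hat\Gamma_j - \beta
#'   \hat\gamma_j)^2}{\sigma_{Yj}^2 + \beta^2 \sigma_{Xj}^2},}
#' which accounts for sampling error on the exposure side and is therefore
#' robust to many weak instruments (assuming pleiotropic effects with mean
#' zero). The standard error comes from the observed curvature at the
#' maximum.
#'
#' @param summaries An `mr_summaries` tibble (at least 2 SNPs).
#' @return An `mr_estimate`; `converged = FALSE` flags an optimum at the
#'   search boundary.
#' @export
mr_raps <- function(summaries) {
  sc <- summary_cols(summaries, 1L, "mr_raps")
  obj <- function(b) -0.5 * sum((sc$bo - b * sc$be)^2 /
                                  (sc$sy^2 + b^2 * sc$sx^2))
  start <- mr_ivw(summaries, "fixed")$beta
  half <- 50 * (1 + abs(start))
  opt <- optimize(obj, interval = c(start - half, start + half),
                  maximum = TRUE, tol = 1e-10)
  beta <- opt$maximum
  converged <- abs(beta - (start - half)) > 1e-6 * half &&
    abs(beta - (start + half)) > 1e-6 * half
  h <- 1e-4 * (1 + abs(beta))
  curv <- (obj(beta + h) - 2 * obj(beta) + obj(beta - h)) / h^2
  se <- sqrt(-1 / curv)
  new_mr_estimate("RAPS", beta, se, sc$J, converged = converged)
}

#' Multivariable MR for two exposures
#'
#' Zero-intercept weighted regression of the outcome associations on the SNP
#' associations with both exposures jointly (weights
#' \eqn{\sigma_{Yj}^{-2}}): each coefficient is the direct causal effect of
#' one exposure holding the other fixed. An exposure whose associations are
#' identically zero is dropped from the fit (its effect is reported as `NA`);
#' a genuinely collinear design is rejected as conditionally weak.
#'
#' @param exposure1,exposure2 `snp_assoc` tibbles for the two exposures.
#' @param outcome `snp_assoc` tibble for the outcome, on the same SNPs and
#'   effect alleles.
#' @return A tibble with one row per exposure: `term`, `beta`, `se`, `pval`,
#'   `n_snps`, plus heterogeneity columns `q`, `q_df`, `q_pval`.
#' @export
mr_mvmr <- function(exposure1, exposure2, outcome) {
  shared <- Reduce(intersect, list(exposure1$snp, exposure2$snp, outcome$snp))
  if (length(shared) < 3L) {
    abort("multivariable MR requires at least 3 shared SNPs.",
          class = "mrcost_error_few_snps")
  }
  b1 <- exposure1$beta[match(shared, exposure1$snp)]
  b2 <- exposure2$beta[match(shared, exposure2$snp)]
  bo <- outcome$beta[match(shared, outcome$snp)]
  sy <- outcome$se[match(shared, outcome$snp)]
  J <- length(shared)
  w <- 1 / sy^2

  X <- cbind(exposure1 = b1, exposure2 = b2)
  nonzero <- apply(X, 2L, function(col) any(col != 0))
  Xf <- X[, nonzero, drop = FALSE]
  if (qr(Xf * sqrt(w))$rank < ncol(Xf)) {
    abort("SNP-exposure associations are collinear (conditionally weak instruments).",
          class = "mrcost_error_rank")
  }
  fit <- wls_known_var(Xf, bo, w)
  q <- fit$rss
  q_df <- J - ncol(Xf)
  infl <- sqrt(max(1, q / q_df))

  beta <- se <- setNames(rep(NA_real_, 2L), colnames(X))
  beta[colnames(Xf)] <- fit$beta
  se[colnames(Xf)] <- fit$se * infl
  tibble(
    term = colnames(X),
    beta = unname(beta),
    se = unname(se),
    pval = two_sided_p(beta / se),
    n_snps = J,
    q = q, q_df = q_df,
    q_pval = pchisq(q, q_df, lower.tail = FALSE)
  )
}

#' Convert an effect from SD units to natural exposure units
#'
#' Divides an estimate expressed per standard deviation of the exposure by
#' the exposure SD (default 4.6 kg/m\eqn{^2}, the median SD of BMI in the
#' source GWAS), so it reads as pounds per kg/m\eqn{^2}. Standard errors are
#' scaled identically.
#'
#' @param x A numeric vector or an `mr_estimate`.
#' @param sd Exposure standard deviation (must be positive).
#' @return The rescaled object.
#' @export
#' @examples
#' sd_to_natural_units(9.2)  # 2.0
sd_to_natural_units <- function(x, sd = 4.6) {
  if (!is.finite(sd) || sd <= 0) {
    abort("`sd` must be positive.", class = "mrcost_error_arg")
  }
  if (inherits(x, "mr_estimate")) {
    x$beta <- x$beta / sd
    x$se <- x$se / sd
    return(x)
  }
  x / sd
}

#' Run the full summary-data estimator suite
#'
#' @param summaries An `mr_summaries` tibble.
#' @param methods Which estimators to run.
#' @param n_boot Bootstrap replicates for the median and mode estimators.
#' @param seed Optional seed for the bootstraps.
#' @return A tibble with one row per estimator (`method`, `beta`, `se`,
#'   `pval`, `n_snps`, `q`, `q_pval`, intercept fields), of class
#'   `mr_estimates`. The underlying `mr_estimate` objects are attached as
#'   attribute `"estimates"`.
#' @export
mr_all <- function(summaries,
                   methods = c("ivw", "egger", "weighted_median",
                               "weighted_mode", "raps"),
                   n_boot = 1000, seed = NULL) {
  maybe_seed(seed)
  fits <- purrr::map(methods, function(m) {
    switch(m,
      ivw = mr_ivw(summaries),
      egger = mr_egger(summaries),
      weighted_median = mr_weighted_median(summaries, n_boot = n_boot),
      weighted_mode = mr_weighted_mode(summaries, n_boot = n_boot),
      raps = mr_raps(summaries),
      abort(paste0("unknown method `", m, "`."), class = "mrcost_error_arg")
    )
  })
  out <- purrr::map_dfr(fits, tidy_estimate_row)
  attr(out, "estimates") <- setNames(fits, methods)
  class(out) <- c("mr_estimates", class(tibble()))
  out
}

tidy_estimate_row <- function(e) {
  tibble(method = e$method, beta = e$beta, se = e$se, pval = e$pval,
         n_snps = e$n_snps, q = e$q, q_pval = e$q_pval,
         intercept = e$intercept, intercept_se = e$intercept_se,
         intercept_pval = e$intercept_pval)
}
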