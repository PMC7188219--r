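# Just-identified IV (single instrument) in closed form, with optional
# within-group demeaning and cluster-robust or heteroskedasticity-robust
# variance. Exogenous covariates are partialled out of y, x and z first
# (Frisch-Waugh), which reproduces the full 2SLS coefficient exactly.
iv_fit <- function(y, x, z, covars = NULL, cluster = NULL, demean_by = NULL) {
  if (!is.null(demean_by)) {
    dm <- function(v) v - ave(v, demean_by)
    y <- dm(y)
    x <- dm(x)
    z <- dm(z)
    if (!is.null(covars)) covars <- apply(covars, 2L, dm)
  }
  Z0 <- if (is.null(covars)) matrix(1, length(y), 1L) else cbind(1, covars)
  qz <- qr(Z0)
  y <- qr.resid(qz, y)
  x <- qr.resid(qz, x)
  z <- qr.resid(qz, z)

  szx <- sum(z * x)
  if (szx == 0) abort("instrument is irrelevant after partialling.",
                      class = "mrcost_error_arg")
  beta <- sum(z * y) / szx
  u <- y - beta * x
  if (is.null(cluster)) {
    meat <- sum((z * u)^2)
  } else {
    zu <- tapply(z * u, cluster, sum)
    g <- length(zu)
    meat <- g / (g - 1) * sum(zu^2)
  }
  se <- sqrt(meat) / abs(szx)
  list(beta = beta, se = se, pval = two_sided_p(beta / se))
}

#' Within-family fixed-effect IV estimate
#'
#' Demeans exposure, cost, allele score and conditioning covariates within
#' family (equivalent to family fixed effects / dummy variables), then
#' estimates the just-identified IV model with the score as instrument.
#' Standard errors are clustered at the family level. Because any
#' family-constant influence (parental genotype, rearing environment,
#' dynastic effects) is removed by the demeaning, the estimate is protected
#' against dynastic bias that inflates population-level MR.
#'
#' @param cohort A cohort tibble with a `family_id` column (e.g. from
#'   [simulate_family_cohort()]). Singleton families are dropped.
#' @param score Allele-score vector (same order as `cohort`).
#' @param condition_on Covariate column names conditioned on (default
#'   `"sex"`).
#' @param fixed_effects Demean within family (`TRUE`, the default); with
#'   `FALSE` the model is estimated on raw data with family-clustered
#'   standard errors only (see [clustered_iv()]).
#' @return A list of class `family_iv`: `beta`, `se`, `pval`,
#'   `n_individuals`, `n_families`, `used_fixed_effects`.
#' @export
family_iv <- function(cohort, score, condition_on = "sex",
                      fixed_effects = TRUE) {
  if (!"family_id" %in% names(cohort)) {
    abort("cohort has no `family_id` column.", class = "mrcost_error_arg")
  }
  fam <- cohort$family_id
  if (fixed_effects) {
    sizes <- table(fam)
    keep <- fam %in% names(sizes)[sizes >= 2L]
    if (!any(keep)) {
      abort("all families are singletons; the fixed-effect model is not identified.",
            class = "mrcost_error_arg")
    }
    cohort <- cohort[keep, ]
    score <- score[keep]
    fam <- fam[keep]
  }
  covars <- if (length(condition_on)) {
    as.matrix(cohort[, condition_on, drop = FALSE])
  } else NULL
  fit <- iv_fit(cohort$cost, cohort$exposure, score, covars = covars,
                cluster = fam, demean_by = if (fixed_effects) fam else NULL)
  structure(list(
    beta = fit$beta, se = fit$se, pval = fit$pval,
    n_individuals = nrow(cohort),
    n_families = length(unique(fam)),
    used_fixed_effects = fixed_effects
  ), class = "family_iv")
}

#' Family-clustered IV without fixed effects
#'
#' The same just-identified IV model as [family_iv()] but without the
#' within-family demeaning: point estimates equal plain 2SLS, with standard
#' errors clustered at the family level.
#'
#' @inheritParams family_iv
#' @return A `family_iv` object with `used_fixed_effects = FALSE`.
#' @export
clustered_iv <- function(cohort, score, condition_on = "sex") {
  family_iv(cohort, score, condition_on = condition_on, fixed_effects = FALSE)
}

#' @export
print.family_iv <- function(x, ...) {
  cat(sprintf("%s IV: beta = %.3f (se %.3f, p = %.3g), %d individuals in %d families\n",
              if (x$used_fixed_effects) "Within-family fixed-effect"
              else "Family-clustered",
              x$beta, x$se, x$pval, x$n_individuals, x$n_families))
  invisible(x)
}

#' Gene-by-environment interaction MR
#'
#' Exploits variation in instrument strength across levels of an
#' environmental covariate: within each level the score-to-exposure (first
#' stage) and score-to-cost (reduced form) associations are estimated, and
#' the reduced-form estimates are regressed on the first-stage estimates
#' across levels with an unconstrained intercept (weights from the
#' reduced-form variances). The slope identifies the causal effect and the
#' intercept the level-constant pleiotropic effect of the score, under the
#' assumption that pleiotropy does not differ between subgroups.
#'
#' @param cohort A cohort tibble.
#' @param score Allele-score vector.
#' @param env Name of the stratifying covariate (default `"deprivation"`,
#'   treated as discrete levels; at least 3 levels required).
#' @return An `mr_estimate` with the intercept fields carrying the constant
#'   pleiotropy estimate; `n_snps` holds the number of environment levels.
#' @export
gxe_mr <- function(cohort, score, env = "deprivation") {
  lev <- sort(unique(cohort[[env]]))
  L <- length(lev)
  if (L < 3L) {
    abort("gene-by-environment MR needs at least 3 environment levels (slope plus intercept must leave residual degrees of freedom).",
          class = "mrcost_error_arg")
  }
  fs <- rf <- rf_se <- fs_se <- numeric(L)
  for (i in seq_len(L)) {
    idx <- cohort[[env]] == lev[i]
    f <- simple_slope(cohort$exposure[idx], score[idx])
    r <- simple_slope(cohort$cost[idx], score[idx])
    fs[i] <- f$beta; fs_se[i] <- f$se
    rf[i] <- r$beta; rf_se[i] <- r$se
  }
  if (max(fs) - min(fs) < 1e-12 * max(1, abs(mean(fs)))) {
    abort("no first-stage variation across environment levels; the interaction instrument is not identified.",
          class = "mrcost_error_weak_interaction")
  }
  wf <- 1 / fs_se^2
  q_fs <- sum(wf * (fs - sum(wf * fs) / sum(wf))^2)
  if (pchisq(q_fs, L - 1L, lower.tail = FALSE) > 0.05) {
    warn("weak evidence of first-stage variation across environment levels; the interaction instrument may be weak.",
         class = "mrcost_warning_weak_interaction")
  }
  fit <- wls_known_var(cbind(1, fs), rf, 1 / rf_se^2)
  fit$beta <- unname(fit$beta)
  q <- fit$rss
  q_df <- L - 2L
  infl <- sqrt(max(1, q / q_df))
  se <- fit$se * infl
  new_mr_estimate("G-by-E interaction", fit$beta[2], se[2], L,
                  q = q, q_df = q_df,
                  q_pval = pchisq(q, q_df, lower.tail = FALSE),
                  intercept = fit$beta[1], intercept_se = se[1],
                  intercept_pval = two_sided_p(fit$beta[1] / se[1]),
                  extra = list(first_stage = fs, reduced_form = rf,
                               levels = lev))
}

#' Conventional (non-IV) estimates of the exposure-cost association
#'
#' The observational comparators: an OLS regression of cost on exposure and
#' covariates with heteroskedasticity-robust (HC1) standard errors, and a
#' gamma GLM with log link fitted to the positive costs, reported as the
#' average marginal effect (mean over individuals of the derivative of
#' predicted cost with respect to exposure, with a delta-method standard
#' error). Both are subject to confounding that valid-instrument MR is not.
#'
#' @param cohort A cohort tibble.
#' @param covariates Covariate column names (default: `sex`, `age`,
#'   `deprivation` where present).
#' @return A tibble with rows labelled `"OLS"` and `"GLM-gamma-AME"`
#'   (columns `method`, `beta`, `se`, `pval`, `n`). If every cost is zero
#'   the GLM row is omitted with a warning.
#' @export
conventional_estimates <- function(cohort, covariates = NULL) {
  if (any(cohort$cost < 0)) {
    abort("costs must be non-negative.", class = "mrcost_error_arg")
  }
  covariates <- covariates %||%
    intersect(c("sex", "age", "deprivation"), names(cohort))
  form <- stats::reformulate(c("exposure", covariates), response = "cost")
  ols <- lm(form, data = cohort)
  vc <- sandwich::vcovHC(ols, type = "HC1")
  b <- coef(ols)[["exposure"]]
  se <- sqrt(vc["exposure", "exposure"])
  out <- tibble(method = "OLS", beta = b, se = se,
                pval = two_sided_p(b / se), n = nrow(cohort))

  pos <- cohort$cost > 0
  if (!any(pos)) {
    warn("all costs are zero; the gamma GLM cannot be fitted.",
         class = "mrcost_warning_glm")
    return(out)
  }
  dpos <- cohort[pos, ]
  fit <- glm(form, data = dpos, family = Gamma(link = "log"))
  mu <- fitted(fit)
  b1 <- coef(fit)[["exposure"]]
  ame <- mean(b1 * mu)
  # delta method: d AME / d beta_k = mean(mu * (1[k = exposure] + b1 * X_k))
  X <- stats::model.matrix(fit)
  grad <- colMeans(mu * (b1 * X))
  grad[["exposure"]] <- grad[["exposure"]] + mean(mu)
  se_ame <- sqrt(drop(t(grad) %*% vcov(fit) %*% grad))
  dplyr::bind_rows(out, tibble(
    method = "GLM-gamma-AME", beta = ame, se = se_ame,
    pval = two_sided_p(ame / se_ame), n = nrow(dpos)
  ))
}
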