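#' Simulate unlinked genotype dosages
#'
#' Draws an `n` by `J` matrix of allele dosages, one column per SNP, with
#' column `j` i.i.d. Binomial(2, `eaf_j`) (Hardy-Weinberg sampling of two
#' independent alleles).
#'
#' @param panel A SNP panel from [snp_panel()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return An integer matrix with entries in \{0, 1, 2\} and columns named by
#'   `snp_id`.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  if (n < 1) abort("`n` must be at least 1.", class = "mrcost_error_arg")
  eaf <- panel$eaf
  if (!all(is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    abort("invalid allele frequency: all `eaf` must lie strictly in (0, 1).",
          class = "mrcost_error_eaf")
  }
  maybe_seed(seed)
  J <- nrow(panel)
  G <- matrix(rbinom(n * J, 2L, rep(eaf, each = n)), nrow = n, ncol = J)
  colnames(G) <- panel$snp_id
  G
}

# effect function f(x) and its derivative (the local causal effect)
effect_fun <- function(x, params) {
  d <- x - params$curvature_center
  params$beta * x + params$beta_quad * d^2 + params$beta_cubic * d^3
}

effect_fun_deriv <- function(x, params) {
  d <- x - params$curvature_center
  params$beta + 2 * params$beta_quad * d + 3 * params$beta_cubic * d^2
}

# Two-part cost draw, calibrated numerically at generation time:
#  - logistic intercept z0 solved so the expected zero-cost share hits target;
#  - gamma log-scale slope s solved so the expected mean cost hits target
#    jointly with the constraint below;
#  - log-scale location solved in closed form so the average derivative of
#    expected cost with respect to the linear predictor is exactly 1, hence
#    d E[cost]/d exposure averages to the structural effect.
two_part_cost <- function(eta, params) {
  n <- length(eta)
  etc <- eta - mean(eta)
  z1 <- params$zero_prob_slope
  target_pos <- 1 - params$zero_share
  z0 <- uniroot(function(z) mean(plogis(z + z1 * etc)) - target_pos,
                interval = c(-30, 30), tol = 1e-10)$root
  p <- plogis(z0 + z1 * etc)

  # mean cost = mean(p*mu) with mu = A exp(s etc) and A fixed by the
  # unit-average-derivative constraint A*mean((z1 p(1-p) + s p) e^{s etc}) = 1
  gap <- function(s) {
    es <- exp(s * etc)
    mean(p * es) - params$cost_mean *
      mean((z1 * p * (1 - p) + s * p) * es)
  }
  s_hi <- 2 / params$cost_mean
  s <- if (gap(0) <= 0) 0 else uniroot(gap, c(0, s_hi), tol = 1e-12)$root
  if (gap(0) <= 0) {
    warn("zero-cost slope too steep to reach the target mean cost; the positive-cost location gradient was set to zero.",
         class = "mrcost_warning_cost_calibration")
  }

  es <- exp(s * etc)
  scale_a <- 1 / mean((z1 * p * (1 - p) + s * p) * es)
  mu <- scale_a * es
  pos <- rbinom(n, 1L, p) == 1L
  cost <- numeric(n)
  k <- params$cost_shape
  cost[pos] <- rgamma(sum(pos), shape = k, scale = mu[pos] / k)
  cost
}

# shared covariate block (independent of genotype by construction)
draw_covariates <- function(n) {
  tibble(
    sex = rbinom(n, 1L, 0.54),
    age = round(rnorm(n, 56.9, 8)),
    deprivation = sample.int(5L, n, replace = TRUE),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n)
  )
}

# assemble a cohort tibble from genotypes under the structural model
build_cohort <- function(G, panel, params, id_prefix = "i",
                         dynastic = NULL, family_id = NULL) {
  n <- nrow(G)
  het <- 2 * panel$eaf * (1 - panel$eaf)
  var_u <- 1 + sum(panel$delta^2 * het)
  g <- drop(G %*% panel$gamma)
  U <- drop(G %*% panel$delta) + rnorm(n)
  covars <- draw_covariates(n)

  var_g <- sum(panel$gamma^2 * het)
  resid_var <- params$exposure_sd^2 - var_g - params$conf_on_x^2 * var_u
  if (resid_var <= 0) {
    abort(paste0("implied residual exposure variance is not positive; ",
                 "the requested variance-explained share and confounder ",
                 "loading exceed the exposure variance."),
          class = "mrcost_error_r2")
  }
  gxe <- 1 + params$gxe_strength * (covars$deprivation - 3) / 2
  x <- (params$exposure_mean - sum(panel$gamma * 2 * panel$eaf)) +
    g * gxe + params$conf_on_x * U + rnorm(n, 0, sqrt(resid_var))

  eta <- effect_fun(x, params) + drop(G %*% panel$alpha) +
    params$conf_on_y * U + params$score_pleiotropy * g
  out <- tibble(id = paste0(id_prefix, seq_len(n)))
  if (!is.null(family_id)) out$family_id <- family_id

  if ("gamma2" %in% names(panel)) {
    g2 <- drop(G %*% panel$gamma2)
    var_g2 <- sum(panel$gamma2^2 * het)
    resid_var2 <- params$exposure2_sd^2 - var_g2 - params$conf_on_x2^2 * var_u
    if (resid_var2 <= 0) {
      abort("implied residual variance of the second exposure is not positive.",
            class = "mrcost_error_r2")
    }
    x2 <- (params$exposure2_mean - sum(panel$gamma2 * 2 * panel$eaf)) +
      g2 + params$conf_on_x2 * U + rnorm(n, 0, sqrt(resid_var2))
    out$exposure2 <- x2
    eta <- eta + params$beta2 * x2
  }
  if (!is.null(dynastic)) eta <- eta + dynastic

  out$exposure <- x
  out$cost <- two_part_cost(eta, params)
  out <- dplyr::bind_cols(out, covars)
  out$confounder <- U
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(G)))
  new_mr_cohort(out, panel)
}

new_mr_cohort <- function(df, panel) {
  structure(df,
            class = c("mr_cohort", class(tibble())),
            panel = panel,
            snp_ids = panel$snp_id)
}

#' Extract the genotype dosage matrix from a cohort
#'
#' @param cohort A cohort tibble from [simulate_cohort()] or [read_cohort()].
#' @return A numeric matrix with one column per SNP.
#' @export
genotype_matrix <- function(cohort) {
  ids <- attr(cohort, "snp_ids")
  if (is.null(ids)) ids <- grep("^rs", names(cohort), value = TRUE)
  as.matrix(cohort[, ids, drop = FALSE])
}

#' Panel attached to a cohort
#' @param cohort A cohort tibble.
#' @return The SNP panel tibble used to simulate the cohort, or `NULL`.
#' @export
cohort_panel <- function(cohort) attr(cohort, "panel")

#' Simulate a cohort of unrelated individuals
#'
#' Generates genotypes under Hardy-Weinberg equilibrium, an exposure from the
#' linear structural model (genetic value + confounder + residual, calibrated
#' to the target mean/SD and variance-explained share), covariates that are
#' independent of genotype, and a per-person-year cost from the two-part
#' model described in [sim_params()]. The hidden confounder is retained in
#' the `confounder` column for testing.
#'
#' @param panel A SNP panel from [snp_panel()].
#' @param params Structural parameters from [sim_params()].
#' @param n Number of individuals.
#' @param seed Optional integer seed; fixing it fixes every output bit-for-bit.
#' @param id_prefix Prefix for individual identifiers (use distinct prefixes
#'   for disjoint samples).
#' @return A cohort tibble of class `mr_cohort` with columns `id`, `exposure`,
#'   optional `exposure2`, `cost`, covariates, `confounder`, and one dosage
#'   column per SNP.
#' @export
#' @examples
#' panel <- snp_panel(n_snps = 5, seed = 1)
#' cohort <- simulate_cohort(panel, sim_params(), n = 100, seed = 2)
#' dplyr::glimpse(cohort[, 1:6])
simulate_cohort <- function(panel, params = sim_params(), n, seed = NULL,
                            id_prefix = "i") {
  maybe_seed(seed)
  G <- simulate_genotypes(panel, n)
  build_cohort(G, panel, params, id_prefix = id_prefix)
}

#' Simulate disjoint exposure and outcome samples
#'
#' Convenience wrapper producing two non-overlapping cohorts from the same SNP
#' panel and structural model, as required for two-sample MR.
#'
#' @inheritParams simulate_cohort
#' @param n_exposure,n_outcome Sample sizes of the two cohorts.
#' @return A list with elements `exposure` and `outcome`, each an `mr_cohort`.
#' @export
simulate_two_sample <- function(panel, params = sim_params(),
                                n_exposure, n_outcome, seed = NULL) {
  maybe_seed(seed)
  list(
    exposure = simulate_cohort(panel, params, n_exposure, id_prefix = "ex"),
    outcome = simulate_cohort(panel, params, n_outcome, id_prefix = "out")
  )
}

# Mendelian transmission: one allele from each parent, uniformly at random
transmit_genotypes <- function(Gm, Gf) {
  n <- nrow(Gm)
  J <- ncol(Gm)
  off <- matrix(rbinom(n * J, 1L, c(Gm) / 2) + rbinom(n * J, 1L, c(Gf) / 2),
                nrow = n, ncol = J)
  colnames(off) <- colnames(Gm)
  off
}

#' Simulate a sibling-family cohort
#'
#' Draws two parents per family (optionally exposure-correlated via rank
#' matching to `mate_corr`), then two offspring per family whose alleles are
#' transmitted uniformly at random from each parent. Offspring costs include
#' `dynastic_effect` pounds per unit of the mid-parental genetic exposure
#' value, emulating environmentally mediated effects of parental genotype
#' that bias population-level MR but are removed by family fixed effects.
#'
#' @inheritParams simulate_cohort
#' @param n_families Number of families (each contributes two siblings).
#' @return An `mr_cohort` tibble of the offspring (two rows per family) with a
#'   `family_id` column. Parental genotypes are attached as attribute
#'   `"parents"` (a list with `Gm`, `Gf`).
#' @export
simulate_family_cohort <- function(panel, params = sim_params(), n_families,
                                   seed = NULL) {
  if (n_families < 1) abort("`n_families` must be at least 1.",
                            class = "mrcost_error_arg")
  if (params$mate_corr < 0 || params$mate_corr >= 1) {
    abort("`mate_corr` must lie in [0, 1).", class = "mrcost_error_arg")
  }
  maybe_seed(seed)
  Gm <- simulate_genotypes(panel, n_families)
  Gf <- simulate_genotypes(panel, n_families)

  if (params$mate_corr > 0) {
    # rank-match parental exposures to the target correlation
    gm <- drop(Gm %*% panel$gamma) + rnorm(n_families, 0, 1)
    gf <- drop(Gf %*% panel$gamma) + rnorm(n_families, 0, 1)
    zm <- qnorm((rank(gm, ties.method = "first") - 0.5) / n_families)
    zt <- params$mate_corr * zm +
      sqrt(1 - params$mate_corr^2) * rnorm(n_families)
    Gf <- Gf[order(gf)[rank(zt, ties.method = "first")], , drop = FALSE]
  }

  midparental <- drop((Gm %*% panel$gamma + Gf %*% panel$gamma)) / 2
  fam <- sprintf("fam%06d", seq_len(n_families))

  G1 <- transmit_genotypes(Gm, Gf)
  G2 <- transmit_genotypes(Gm, Gf)
  G <- rbind(G1, G2)
  ord <- rep(seq_len(n_families), times = 2)
  dynastic <- params$dynastic_effect * midparental[ord]
  cohort <- build_cohort(G, panel, params, id_prefix = "sib",
                         dynastic = dynastic, family_id = fam[ord])
  cohort <- cohort[order(cohort$family_id, cohort$id), ]
  cohort <- new_mr_cohort(cohort, panel)
  attr(cohort, "parents") <- list(Gm = Gm, Gf = Gf, family_id = fam)
  cohort
}
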