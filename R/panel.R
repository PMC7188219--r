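#' Build a synthetic SNP instrument panel
#'
#' Constructs a panel of independent biallelic SNPs with per-allele effects on
#' the exposure (`gamma`, kg/m\eqn{^2} per effect allele) and optional direct
#' (pleiotropic) effects on the cost outcome (`alpha`, pounds per allele per
#' person-year). Effect sizes are drawn as half-normal magnitudes and rescaled
#' so that, under Hardy-Weinberg genotype frequencies, the panel jointly
#' explains `r2_target` of the exposure variance. The default of 79 SNPs
#' explaining 1.74\% of BMI variance mirrors the instrument set used in
#' large-scale adiposity MR studies.
#'
#' Pleiotropy presets:
#' \describe{
#'   \item{`"none"`}{all `alpha = 0`; every SNP is a valid instrument.}
#'   \item{`"balanced"`}{`alpha` drawn with mean zero; exclusion restriction
#'     violated SNP-by-SNP but not on average.}
#'   \item{`"directional"`}{a fraction `prop_invalid` of SNPs receive
#'     `alpha` with non-zero mean `alpha_mean`, drawn independently of
#'     `gamma` so the InSIDE condition holds.}
#'   \item{`"confounder"`}{SNPs act on the unobserved confounder (`delta`
#'     column), which in turn affects both exposure and cost; instrument
#'     strength and direct effect are then correlated, violating InSIDE.}
#' }
#'
#' @param n_snps Number of independent SNPs.
#' @param r2_target Share of exposure variance jointly explained by the panel,
#'   in (0, 1).
#' @param exposure_sd Population standard deviation of the exposure the panel
#'   is calibrated against (kg/m\eqn{^2}).
#' @param eaf_range Range of effect-allele frequencies to draw from.
#' @param pleiotropy Pleiotropy preset; see Details.
#' @param alpha_mean,alpha_sd Mean and SD of the direct effects (pounds per
#'   allele per person-year) for pleiotropic SNPs.
#' @param prop_invalid Fraction of SNPs given a directional direct effect
#'   under the `"directional"` preset.
#' @param confounder_r2 Under the `"confounder"` preset, share of the
#'   confounder's unit variance attributable to the panel.
#' @param second_trait If `TRUE`, add per-allele effects `gamma2` on a second
#'   exposure (body-fat percentage) for multivariable MR simulations.
#' @param r2_target2 Variance share of the second exposure explained by the
#'   panel.
#' @param exposure2_sd SD of the second exposure (percentage points).
#' @param gamma_cor Correlation between the magnitudes of `gamma` and
#'   `gamma2` across SNPs.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, `pos_bp`,
#'   `effect_allele`, `other_allele`, `eaf`, `gamma`, `alpha`, `delta`
#'   (per-allele effect on the latent confounder) and, if requested, `gamma2`.
#' @export
#' @examples
#' panel <- snp_panel(n_snps = 10, seed = 1)
#' panel
snp_panel <- function(n_snps = 79,
                      r2_target = 0.0174,
                      exposure_sd = 4.6,
                      eaf_range = c(0.05, 0.5),
                      pleiotropy = c("none", "balanced", "directional", "confounder"),
                      alpha_mean = 15,
                      alpha_sd = 7.5,
                      prop_invalid = 1,
                      confounder_r2 = 0.5,
                      second_trait = FALSE,
                      r2_target2 = 0.005,
                      exposure2_sd = 8.5,
                      gamma_cor = 0.6,
                      seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (!is.finite(r2_target) || r2_target <= 0 || r2_target >= 1) {
    abort("`r2_target` (variance-explained share) must lie strictly in (0, 1).",
          class = "mrcost_error_r2")
  }
  if (n_snps < 1) abort("`n_snps` must be at least 1.", class = "mrcost_error_arg")
  maybe_seed(seed)

  eaf <- runif(n_snps, eaf_range[1], eaf_range[2])
  het <- 2 * eaf * (1 - eaf)

  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_snps, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))

  raw <- abs(rnorm(n_snps))
  gamma <- raw * sqrt(r2_target * exposure_sd^2 / sum(raw^2 * het))

  alpha <- numeric(n_snps)
  delta <- numeric(n_snps)
  if (pleiotropy == "balanced") {
    alpha <- rnorm(n_snps, 0, alpha_sd)
    alpha <- alpha - mean(alpha)  # exactly zero-mean direct effects
  } else if (pleiotropy == "directional") {
    n_bad <- max(1L, round(prop_invalid * n_snps))
    bad <- sample.int(n_snps, n_bad)
    alpha[bad] <- rnorm(n_bad, alpha_mean, alpha_sd)
  } else if (pleiotropy == "confounder") {
    d <- abs(rnorm(n_snps))
    delta <- d * sqrt(confounder_r2 / sum(d^2 * het))
  }

  out <- tibble(
    snp_id = sprintf("rs%05d", seq_len(n_snps)),
    chrom = as.integer((seq_len(n_snps) - 1L) %% 22L + 1L),
    pos_bp = as.integer(1e6 + 2e6 * ((seq_len(n_snps) - 1L) %/% 22L)),
    effect_allele = unname(ea),
    other_allele = unname(oa),
    eaf = eaf,
    gamma = gamma,
    alpha = alpha,
    delta = delta
  )
  if (second_trait) {
    raw2 <- gamma_cor * raw + sqrt(1 - gamma_cor^2) * abs(rnorm(n_snps))
    out$gamma2 <- raw2 * sqrt(r2_target2 * exposure2_sd^2 / sum(raw2^2 * het))
  }
  out
}

#' Structural parameters for cohort simulation
#'
#' Bundles the ground-truth parameters of the data-generating model: a linear
#' structural exposure model with an unobserved standard-normal confounder, and
#' a two-part (logistic/gamma) cost model whose conditional-mean linear
#' predictor carries the causal effect, the pleiotropic direct effects and the
#' confounder loading. The positive-cost location is solved at generation time
#' so that the population-average marginal effect of exposure on expected cost
#' equals `beta` exactly (for the linear effect function), giving a known
#' ground truth despite the zero mass and skew.
#'
#' The exposure->cost effect function is
#' \deqn{f(x) = \beta x + \beta_{quad}(x - x_0)^2 + \beta_{cubic}(x - x_0)^3,}
#' so its derivative (the local causal effect recovered by stratified MR) is
#' constant when both curvature terms are zero, linear in \eqn{x} under
#' `beta_quad`, and quadratic in \eqn{x} under `beta_cubic`.
#'
#' @param beta Causal effect of exposure on cost (pounds per kg/m\eqn{^2} per
#'   person-year).
#' @param beta_quad,beta_cubic Curvature terms of the effect function (pounds
#'   per unit\eqn{^2} and per unit\eqn{^3}).
#' @param curvature_center Centre \eqn{x_0} of the curvature terms (kg/m\eqn{^2}).
#' @param conf_on_x Confounder loading on exposure (kg/m\eqn{^2} per confounder SD).
#' @param conf_on_y Confounder loading on the cost linear predictor (pounds).
#' @param exposure_mean,exposure_sd Target exposure mean and SD (kg/m\eqn{^2}).
#' @param zero_share Target share of individuals with zero annual cost.
#' @param zero_prob_slope Logistic slope of the any-cost probability on the
#'   (centred) cost linear predictor, per pound.
#' @param cost_mean Target mean cost (pounds per person-year).
#' @param cost_shape Gamma shape of the positive-cost distribution. The
#'   default 1.03 reproduces a median cost of ~88 when 45\% of costs are zero
#'   and the mean is 479.
#' @param dynastic_effect Pounds added to an offspring's cost linear predictor
#'   per unit of mid-parental genetic exposure value.
#' @param mate_corr Exposure correlation between mates, in [0, 1).
#' @param beta2 Causal effect of the second exposure (body-fat \%) on cost.
#' @param conf_on_x2 Confounder loading on the second exposure.
#' @param exposure2_mean,exposure2_sd Mean and SD of the second exposure.
#' @param gxe_strength Relative modulation of the genetic effect on exposure
#'   across deprivation quintiles (0 = no gene-environment interaction).
#' @param score_pleiotropy Constant direct effect of the genetic exposure value
#'   on the cost linear predictor (pounds per unit), shared across strata.
#'
#' @return A list of class `mr_sim_params`.
#' @export
sim_params <- function(beta = 20,
                       beta_quad = 0,
                       beta_cubic = 0,
                       curvature_center = 21.4,
                       conf_on_x = 1.38,
                       conf_on_y = 60,
                       exposure_mean = 27.4,
                       exposure_sd = 4.6,
                       zero_share = 0.45,
                       zero_prob_slope = 0.002,
                       cost_mean = 479,
                       cost_shape = 1.03,
                       dynastic_effect = 0,
                       mate_corr = 0,
                       beta2 = 0,
                       conf_on_x2 = 1,
                       exposure2_mean = 31.3,
                       exposure2_sd = 8.5,
                       gxe_strength = 0,
                       score_pleiotropy = 0) {
  if (!is.finite(cost_shape) || cost_shape <= 0) {
    abort("`cost_shape` must be positive.", class = "mrcost_error_arg")
  }
  if (!is.finite(mate_corr) || mate_corr < 0 || mate_corr >= 1) {
    abort("`mate_corr` must lie in [0, 1).", class = "mrcost_error_arg")
  }
  monetary <- c(beta, beta_quad, beta_cubic, conf_on_y, cost_mean,
                dynastic_effect, beta2, score_pleiotropy)
  if (!all(is.finite(monetary))) {
    abort("all monetary parameters must be finite.", class = "mrcost_error_arg")
  }
  if (!is.finite(zero_share) || zero_share <= 0 || zero_share >= 1) {
    abort("`zero_share` must lie in (0, 1).", class = "mrcost_error_arg")
  }
  structure(list(
    beta = beta, beta_quad = beta_quad, beta_cubic = beta_cubic,
    curvature_center = curvature_center,
    conf_on_x = conf_on_x, conf_on_y = conf_on_y,
    exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    zero_share = zero_share, zero_prob_slope = zero_prob_slope,
    cost_mean = cost_mean, cost_shape = cost_shape,
    dynastic_effect = dynastic_effect, mate_corr = mate_corr,
    beta2 = beta2, conf_on_x2 = conf_on_x2,
    exposure2_mean = exposure2_mean, exposure2_sd = exposure2_sd,
    gxe_strength = gxe_strength, score_pleiotropy = score_pleiotropy
  ), class = "mr_sim_params")
}
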