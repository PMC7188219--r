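# mrcost

Mendelian-randomization (MR) estimation of the causal effect of adiposity
(BMI, kg/m²) on inpatient hospital costs (£ per person-year), for health
economists and genetic epidemiologists who want instrumental-variable cost
estimates with the full set of pleiotropy-robust sensitivity analyses — and a
synthetic biobank generator so the whole pipeline runs and is tested without
restricted-access data.

## The model

Germline variants $G_{ij}$ instrument the exposure:

$$X_i = \sum_j \gamma_j G_{ij} + \varepsilon_{Xi}, \qquad
Y_i = \beta X_i + \sum_j \alpha_j G_{ij} + \varepsilon_{Yi},$$

where $\beta$ is the causal effect of interest and $\alpha_j$ are direct
(pleiotropic) SNP effects that violate the exclusion restriction when
non-zero. From per-SNP summary pairs $(\hat\gamma_j, \hat\Gamma_j)$ the
package provides the Wald ratio, the inverse-variance-weighted (IVW)
estimator

$$\hat\beta_{IVW} = \frac{\sum_j \hat\gamma_j^2\sigma_{Yj}^{-2}\hat\beta_j}
{\sum_j \hat\gamma_j^2\sigma_{Yj}^{-2}}, \qquad
\hat\beta_j = \hat\Gamma_j/\hat\gamma_j,$$

Cochran's Q, MR-Egger (directional pleiotropy), the penalized weighted
median (valid if >50% of weight is valid), the weighted mode (zero modal
pleiotropy), the robust adjusted profile score (weak instruments),
multivariable MR, non-linear MR by residual stratification into 100
quantile-specific local average causal effects, within-family fixed-effect
IV with family-clustered errors (dynastic effects), gene-by-environment
interaction MR, and OLS / gamma-GLM observational comparators.

The simulator reproduces the study design: 79 independent SNPs jointly
explaining 1.74% of BMI variance (mean 27.4, SD 4.6), a hidden confounder,
and a two-part cost outcome (45% zeros, mean £479, median £88 per
person-year) calibrated so the average marginal effect of BMI on expected
cost equals the chosen $\beta$ exactly.

## Worked example

```r
library(mrcost)

panel  <- snp_panel(seed = 11)                     # 79 instruments
sims   <- simulate_two_sample(panel, sim_params(beta = 20),
                              n_exposure = 100000, n_outcome = 50000,
                              seed = 42)
summ   <- two_sample_summaries(sims$exposure, sims$outcome)
mr_all(summ, n_boot = 500, seed = 1)
```

```
  method                              beta    se     pval n_snps    q q_pval
1 IVW (multiplicative random effects) 25.6  5.83 1.10e-05     79 89.3  0.180
2 MR-Egger                            16.7  9.24 7.10e-02     79 87.5  0.194
3 Penalized weighted median           12.1  9.87 2.19e-01     79   NA     NA
4 Weighted mode                       17.4 93.72 8.53e-01     79   NA     NA
5 RAPS                                26.9  5.61 1.70e-06     79   NA     NA
```

The true simulated effect is £20 per BMI unit per person-year; every
estimator's interval covers it, with the mode (as in real applications) much
the least precise. The Egger intercept (`tidy(mr_egger(summ))`: 1.42, se
1.14, p = 0.21) is consistent with zero, as it should be in this
no-pleiotropy scenario, and the allele-score first-stage F is 879
(`instrument_diagnostics()`), with the SNPs explaining 1.9% of exposure
variance. A policy projection for 50 million adults and a one-unit BMI
shift follows directly:

```r
policy_cost_projection(50e6, 1, 18.85)$total_cost
#> [1] 942500000
```

Individual-level sensitivity analyses use the cohort directly:

```r
score  <- allele_score(sims$outcome, panel[, c("snp_id", "gamma")])
strata <- stratify_lace(sims$outcome, score, K = 100)   # non-linear MR
nonlinearity_tests(strata)
fam    <- simulate_family_cohort(panel, sim_params(dynastic_effect = 30),
                                 n_families = 5000, seed = 7)
family_iv(fam, allele_score(fam, panel[, c("snp_id", "gamma")]))
```

`plot_mr_scatter()`, `plot_mr_forest()` and `autoplot()` on LACE strata give
the standard displays; `tidy()`/`glance()` return broom-style tibbles.

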