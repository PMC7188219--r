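---
title: "Methods: Mendelian randomization for hospital costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization for hospital costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcost)
```

## The problem

Estimates of how much an extra unit of body mass index (BMI, kg/m²) adds to
annual inpatient hospital costs are confounded in observational data: the
unobserved determinants of adiposity (behaviour, environment, morbidity) also
drive hospital use. Mendelian randomization (MR) treats germline genetic
variants as instrumental variables: conditional on parental genotype, alleles
are assigned at random at conception, so a variant that raises BMI provides
exogenous variation in lifetime exposure. `mrcost` implements the full MR
toolkit for this question — two-sample summary-data estimators, pleiotropy
diagnostics, non-linear MR, within-family models and observational
comparators — together with a synthetic biobank generator so every stage is
testable without restricted-access data.

## Structural model

For individual $i$ and SNPs $j = 1,\dots,J$ with dosages $G_{ij} \in
\{0,1,2\}$:

$$X_i = \mu_X + \sum_j \gamma_j G_{ij} + \lambda_X U_i + \varepsilon_{Xi},
\qquad
\eta_i = f(X_i) + \sum_j \alpha_j G_{ij} + \lambda_Y U_i,$$

where $U_i$ is a standard-normal unobserved confounder, $\alpha_j$ are direct
(horizontally pleiotropic) SNP effects on costs, and
$f(x) = \beta x + \beta_q (x - x_0)^2 + \beta_c (x - x_0)^3$ is the
exposure–cost effect function (linear by default, $f'(x) \equiv \beta$). The
$\gamma_j$ are drawn as half-normal magnitudes and rescaled so the panel
explains a configurable share of exposure variance (default 1.74% with
$J = 79$ SNPs, exposure mean 27.4 and SD 4.6 kg/m²), matching the instrument
strength reported for large adiposity GWAS panels.

### Two-part cost model

Annual inpatient costs are zero for many people and right-skewed otherwise.
Costs are drawn in two parts from the linear predictor $\eta_i$:

* any-cost indicator: $\Pr(\text{cost} > 0) = \text{logit}^{-1}(z_0 + z_1
  \tilde\eta_i)$ with $\tilde\eta$ centred; $z_1$ (default 0.002 per £)
  allocates part of the marginal effect to the extensive margin;
* positive costs: Gamma with shape $k$ (default 1.03) and mean
  $\mu_i = A e^{s\tilde\eta_i}$.

Three constants are solved at generation time: $z_0$ so the zero-cost share
hits its target (default 45%), $s$ so the mean cost hits its target (default
£479/person-year), and $A$ in closed form so that the population-average
derivative of expected cost with respect to $\eta$ is exactly 1 — hence the
average marginal effect of exposure on expected cost equals $\beta$ exactly
under the linear effect function. The shape default $k = 1.03$ is the value
for which a 45% zero mass and mean £479 imply a median cost of £88, the
published profile this generator emulates. With these targets the implied
cost standard deviation is ≈ £770.

What the generator does *not* emulate: linkage disequilibrium between
variants (SNPs are independent), episode-level cost construction, age- or
time-varying genetic effects, and the extreme upper tail of real cost data.
Passing tests therefore demonstrate correctness of the estimators under the
assumed structural model, not robustness to every feature of real biobank
data.

### Families and dynastic effects

`simulate_family_cohort()` draws two parents per family (optionally
rank-matched on exposure to a target mate correlation) and two offspring,
each allele transmitted uniformly at random from the corresponding parent.
Offspring cost linear predictors add `dynastic_effect` pounds per unit of the
mid-parental genetic exposure value $(g_m + g_f)/2$, emulating
environmentally mediated effects of parental genotype. Because offspring
genotype correlates with the mid-parental value ($\mathrm{cov} =
\mathrm{var}(G_j)/2$ per SNP), a dynastic effect $d$ inflates population-level
IVW by about $d/2$, while within-family demeaning removes it — the bias the
family fixed-effect estimator exists to avoid.

## Estimators

All summary-data estimators consume aligned per-SNP pairs
$(\hat\gamma_j, \sigma_{Xj}, \hat\Gamma_j, \sigma_{Yj})$.

* **Wald ratio** $\hat\Gamma_j/\hat\gamma_j$ with first-order standard error
  $\sigma_{Yj}/|\hat\gamma_j|$ (NOME); a second-order correction is available
  behind a flag but off by default.
* **IVW**: inverse-variance-weighted ratio average, identical to
  zero-intercept WLS of $\hat\Gamma$ on $\hat\gamma$ with weights
  $\sigma_{Yj}^{-2}$. Random-effects inference uses a *multiplicative*
  overdispersion $\sqrt{\max(1, Q/(J-1))}$, which never shrinks the standard
  error below fixed effects.
* **Cochran's Q** $= \sum_j \hat\gamma_j^2\sigma_{Yj}^{-2} (\hat\beta_j -
  \hat\beta_{IVW})^2 \sim \chi^2_{J-1}$ under instrument validity.
* **MR-Egger**: WLS with intercept after orienting $\hat\gamma_j > 0$; the
  intercept estimates average directional pleiotropy and is consistent under
  InSIDE (instrument strength independent of direct effects).
* **Penalized weighted median**: the ratio at 50% of cumulative standardized
  weight, interpolating linearly between order statistics (ties broken by
  SNP id). Weights $\hat\gamma_j^2 \sigma_{Yj}^{-2}$ are multiplied by
  $\min(1, 20\,p_j)$, with $p_j$ the upper $\chi^2_1$ probability of SNP $j$'s
  heterogeneity contribution at the unpenalized estimate. The constant 20 and
  the parametric bootstrap (normal draws around the summary pairs, default
  1,000 replicates, seeded) are declared defaults; the source methods leave
  them to the implementation.
* **Weighted mode**: maximizer of a Gaussian-kernel weighted density of the
  ratios, bandwidth `bandwidth_factor` × the modified Silverman rule
  $0.9\min(\mathrm{sd}, \mathrm{mad})J^{-1/5}$, evaluated on a 512-point grid
  spanning the ratios ± 3 bandwidths; bootstrap standard errors as above.
* **RAPS**: maximizes $\ell(\beta) = -\tfrac12\sum_j (\hat\Gamma_j - \beta
  \hat\gamma_j)^2/(\sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2)$, with the standard
  error from observed curvature. Accounting for $\sigma_X$ makes it robust to
  many weak instruments when pleiotropy has mean zero.
* **Multivariable MR**: zero-intercept WLS of $\hat\Gamma$ on two exposures'
  association vectors jointly; collinear designs are rejected as
  conditionally weak, and an identically-zero exposure column is dropped so
  the fit nests the univariable case.

### Weak instruments: what to expect at small sample sizes

The estimator suite is exercised in simulation at $n = 20{,}000$ per sample.
With 79 SNPs jointly explaining 1.74% of exposure variance this implies a
mean per-SNP first-stage F of $nR^2/J \approx 4.4$ — a weak-instrument
regime. Because $E[\hat\gamma_j^2] = \gamma_j^2 + \sigma_{Xj}^2$, IVW then
attenuates by roughly $\bar F/(\bar F + 1) \approx 0.81$, i.e. about −£3.7 on
a true effect of £20; the median and mode estimators inherit a similar
denominator bias. RAPS, which models $\sigma_X$ explicitly, stays centred.
At biobank/GWAS scale ($n$ in the hundreds of thousands) the same attenuation
is below 2% and all estimators agree. Monte-Carlo results at desk scale
should be read with this in mind: it is a property of the regime, not an
implementation artefact.

## Harmonization, clumping, scores

Harmonization aligns the exposure and outcome association tables on a common
effect allele: swapped alleles flip the outcome effect sign and complement
the frequency; palindromic SNPs (A/T, C/G) are reconciled by frequency and
dropped when either frequency lies within 0.5 ± 0.08 (a declared,
configurable default — the window is not fixed by the source methods);
irreconcilable alleles are dropped as triallelic. Every SNP's disposition is
recorded, and harmonizing already-harmonized inputs is a no-op. Greedy LD
clumping visits SNPs by ascending p-value (SNP id as deterministic
tie-break) and drops any SNP within 10,000 kb and $R^2 \ge 0.001$ of a kept
SNP; positions are 1-based. Allele scores are weighted dosage sums with
weights oriented to the exposure-increasing allele; effects estimated per SD
of exposure convert to natural units by dividing by the exposure SD
(default 4.6).

## Non-linear MR

Exposure is residualized on the allele score, the cohort is split into
$K = 100$ equal-size residual quantiles (stable sort, row order as
tie-break), and each stratum's local average causal effect (LACE) is the
stratum-specific score→cost association divided by the *whole-sample*
score→exposure association — the whole-sample denominator matches the method
this analysis follows, and its constancy is itself tested via the
heterogeneity of per-stratum first stages. Four tests probe the LACE profile
by weighted meta-regression with standard errors treated as known:
degree-1 fractional polynomials (powers $\{-2,-1,-0.5,0,0.5,1,2,3\}$, 0 =
log; likelihood-ratio against linear on 1 df), degree-2 against degree-1
(2 df, repeated powers using the log-multiplied second term), a quadratic
test (z-test of the squared term), and a trend test (z-test of the linear
slope). Basis columns are centred and rescaled before fitting for numerical
conditioning; deviances and z statistics are invariant to this.

Note a geometric subtlety: a *quadratic* cost–exposure function has a
*linear* LACE profile, which the trend test detects; curvature of the LACE
profile itself — what the quadratic term in the meta-regression tests —
corresponds to a cubic term in the cost function. The generator therefore
exposes `beta_cubic` for power studies of the quadratic test, with
`beta_cubic = 1` (centre 21.4 kg/m²) as the "strong curvature" scenario:
chosen a priori so the quadratic z statistic is ≈ 10 at $n = 50{,}000$,
giving power near 1 while leaving calibration scenarios untouched.

Under the two-part cost model the local effect drifts slightly with $\eta$
even when $f' \equiv \beta$ (the log-link intensity margin is convex), so
the linear-scenario type-I runs use $n = 20{,}000$, where the drift is well
inside one standard error of the trend test.

## Within-family and G×E models

The within-family estimator demeans exposure, cost, score and conditioning
covariates (sex by default) within family — numerically identical to family
dummy variables — then solves the just-identified IV estimate in closed form
on the partialled data, with standard errors clustered by family
(with a $G/(G-1)$ small-sample factor). The clustered-only variant skips
demeaning. The 2SLS is deliberately implemented in closed form so an exact
dummy-variable oracle is available in the tests.

Gene-by-environment MR stratifies on deprivation quintiles (the default
environment), estimates per-stratum first-stage and reduced-form score
associations, and regresses reduced form on first stage across strata with
an intercept: the slope is the causal effect, the intercept the
level-constant pleiotropy. Exactly constant first stages are reported as
non-identified; weak first-stage variation (heterogeneity p > 0.05) warns.
The generator's `gxe_strength` parameter scales the genetic effect across
quintiles to create the identifying variation.

## Conventional comparators

OLS of cost on exposure and covariates (HC1 robust errors) and a gamma GLM
with log link on the positive costs, summarised as the average marginal
effect $\mathrm{mean}_i\, \partial \hat E[\text{cost}_i]/\partial x_i$ with a
delta-method standard error. Both inherit confounding bias of about
$\lambda_X \lambda_Y / \mathrm{var}(X) \approx$ +£3.9 under the default
generator, which is the point of the comparison.

## Reproducibility and problem sizes

Every stochastic routine accepts a seed, and fixing the seed fixes outputs
bit-for-bit; `run_pipeline()` writes a versioned JSON summary reproducible
from (config, seed), and rejects unknown configuration keys. The Monte-Carlo
test batteries use problem sizes chosen as a compromise between resolution
and runtime on a single CPU: 200 replicates at $n = 20{,}000$ per sample for
parameter recovery; 100 replicates for robustness ordering and pleiotropy
detection with the study's asymmetric design (GWAS-scale exposure side,
$n = 100{,}000$, against a 20,000-person outcome cohort — weak exposure-side
estimates would otherwise destabilise the internal effect-allele
orientation); 500 replicates at 20,000/4,000 for Q calibration (the precise
exposure side keeps the NOME term negligible, as the $\chi^2$ reference
assumes); 100 replicates of 5,000 families for dynastic bias; and 50/25
replicates for non-linearity calibration/power. Bootstraps inside these
loops use 100–500 replicates; user-facing defaults are 1,000.

## Known limitations

* No LD-aware simulation or proxy-SNP lookup; instruments are independent by
  construction.
* The ratio standard error defaults to the NOME first-order form; the
  second-order option changes little at GWAS-scale precision.
* The G×E identifying assumption (pleiotropy constant across strata) is not
  testable within the model; the intercept only captures the constant part.
* Family models take family identifiers as given; kinship inference is out
  of scope.
* Costs are simulated per person-year with no censoring or follow-up
  heterogeneity.
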