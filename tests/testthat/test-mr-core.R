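test_that("Wald ratios follow the delta-method arithmetic", {
  s <- make_summaries(beta_exposure = c(0.2, 0.25),
                      beta_outcome = c(0, 0.5),
                      se_outcome = c(0.5, 0.1))
  r <- wald_ratios(s)
  expect_equal(r$ratio, c(0, 2))
  expect_equal(r$se_ratio[2], 0.4)

  s0 <- make_summaries(beta_exposure = c(0, 0.2), beta_outcome = c(1, 1))
  expect_error(wald_ratios(s0), class = "mrcost_error_zero_gamma")

  # second-order option adds the exposure-side variance term
  r2 <- wald_ratios(s, second_order = TRUE)
  expect_true(all(r2$se_ratio >= r$se_ratio))
})

test_that("IVW equals the no-intercept WLS oracle and reduces correctly", {
  set.seed(7)
  s <- make_summaries(beta_exposure = runif(8, 0.05, 0.3),
                      beta_outcome = rnorm(8, 2, 1),
                      se_exposure = runif(8, 0.01, 0.05),
                      se_outcome = runif(8, 0.5, 2))
  ivw <- mr_ivw(s, "fixed")
  oracle <- lm(beta_outcome ~ 0 + beta_exposure, data = s,
               weights = 1 / s$se_outcome^2)
  expect_equal(ivw$beta, unname(coef(oracle)), tolerance = 1e-10)

  # single SNP reduces exactly to the Wald ratio
  s1 <- s[1, ]
  ivw1 <- mr_ivw(s1)
  r1 <- wald_ratios(s1)
  expect_equal(ivw1$beta, r1$ratio)
  expect_equal(ivw1$se, r1$se_ratio)

  # homogeneous ratios: Q = 0 and random-effects se equals fixed-effects se
  sh <- make_summaries(beta_exposure = c(0.1, 0.2, 0.3),
                       beta_outcome = 2 * c(0.1, 0.2, 0.3))
  ivw_h <- mr_ivw(sh, "random")
  expect_equal(ivw_h$q, 0, tolerance = 1e-20)
  expect_equal(ivw_h$se, ivw_h$se_fixed)
})

test_that("IVW is invariant to re-orienting SNPs and monetarily equivariant", {
  set.seed(8)
  s <- make_summaries(beta_exposure = runif(10, 0.05, 0.3),
                      beta_outcome = rnorm(10, 2, 1),
                      se_outcome = runif(10, 0.5, 2))
  base <- mr_ivw(s)
  flipped <- s
  flip <- c(1, 3, 7)
  flipped$beta_exposure[flip] <- -flipped$beta_exposure[flip]
  flipped$beta_outcome[flip] <- -flipped$beta_outcome[flip]
  expect_equal(mr_ivw(flipped)$beta, base$beta, tolerance = 1e-12)

  for (fit_fun in list(function(x) mr_ivw(x),
                       function(x) mr_egger(x),
                       function(x) mr_raps(x),
                       function(x) mr_weighted_median(x, n_boot = 150, seed = 1),
                       function(x) mr_weighted_mode(x, n_boot = 150, seed = 1))) {
    scaled <- s
    scaled$beta_outcome <- 3 * scaled$beta_outcome
    scaled$se_outcome <- 3 * scaled$se_outcome
    a <- fit_fun(s)
    b <- fit_fun(scaled)
    expect_equal(b$beta, 3 * a$beta, tolerance = 2e-2)
    expect_equal(b$se, 3 * a$se, tolerance = 0.1)
  }
})

test_that("Cochran's Q behaves at its boundary cases", {
  sh <- make_summaries(beta_exposure = c(0.1, 0.2, 0.3),
                       beta_outcome = 2 * c(0.1, 0.2, 0.3))
  qres <- mr_cochran_q(sh, beta_ref = 2)
  expect_equal(qres$q, 0, tolerance = 1e-20)
  expect_equal(qres$pval, 1)
  expect_equal(qres$df, 2L)

  expect_error(mr_cochran_q(sh[1, ]), class = "mrcost_error_few_snps")

  # one displaced SNP dominates the contributions
  sd_ <- make_summaries(beta_exposure = rep(0.2, 5),
                        beta_outcome = c(rep(0.4, 4), 0.4 + 10 * 1 / 0.2 * 0.2))
  qd <- mr_cochran_q(sd_, beta_ref = 2)
  contrib <- attr(qd, "contributions")
  expect_equal(which.max(contrib), 5L, ignore_attr = TRUE)
  expect_gt(max(contrib) / sum(contrib), 0.9)
})

test_that("MR-Egger equals the with-intercept WLS oracle and fits exact lines", {
  # three collinear points: slope/intercept exact, residual Q = 0
  be <- c(0.1, 0.2, 0.3)
  s <- make_summaries(beta_exposure = be, beta_outcome = 1.5 + 2 * be)
  eg <- mr_egger(s)
  expect_equal(eg$beta, 2, tolerance = 1e-10)
  expect_equal(eg$intercept, 1.5, tolerance = 1e-10)
  expect_equal(eg$q, 0, tolerance = 1e-16)

  set.seed(9)
  s2 <- make_summaries(beta_exposure = runif(9, 0.05, 0.3),
                       beta_outcome = rnorm(9, 2, 1),
                       se_outcome = runif(9, 0.5, 2))
  eg2 <- mr_egger(s2)
  oracle <- lm(beta_outcome ~ beta_exposure, data = s2,
               weights = 1 / s2$se_outcome^2)
  expect_equal(eg2$beta, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(eg2$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)

  expect_error(mr_egger(s2[1:2, ]), class = "mrcost_error_few_snps")
})

test_that("weighted median matches the brute-force cumulative-weight oracle", {
  # five equal weights, ratios 1,2,3,4,100 -> middle ratio
  s <- make_summaries(beta_exposure = rep(0.2, 5),
                      beta_outcome = 0.2 * c(1, 2, 3, 4, 100))
  wm <- mr_weighted_median(s, penalized = FALSE, n_boot = 150, seed = 1)
  expect_equal(wm$beta, 3)

  # random weights against the independent oracle
  set.seed(10)
  for (rep in 1:5) {
    be <- runif(7, 0.05, 0.3)
    sy <- runif(7, 0.5, 2)
    bo <- rnorm(7, 2 * be, 0.5)
    s2 <- make_summaries(be, bo, se_outcome = sy)
    wm2 <- mr_weighted_median(s2, penalized = FALSE, n_boot = 150, seed = rep)
    expect_equal(wm2$beta, oracle_weighted_median(bo / be, be^2 / sy^2),
                 tolerance = 1e-10)
  }

  # identical ratios: estimate exact, bootstrap se small
  sc <- make_summaries(beta_exposure = c(0.1, 0.2, 0.3),
                       beta_outcome = 2.5 * c(0.1, 0.2, 0.3),
                       se_exposure = rep(1e-6, 3),
                       se_outcome = rep(1e-4, 3))
  wc <- mr_weighted_median(sc, n_boot = 150, seed = 2)
  expect_equal(wc$beta, 2.5, tolerance = 1e-6)
  expect_lt(wc$se, 0.05)

  expect_warning(mr_weighted_median(s, n_boot = 50, seed = 1))
})

test_that("weighted mode finds the dominant cluster", {
  # all ratios equal -> estimate equals the common value
  sc <- make_summaries(beta_exposure = c(0.1, 0.2, 0.4),
                       beta_outcome = 2 * c(0.1, 0.2, 0.4))
  expect_equal(mr_weighted_mode(sc, n_boot = 150, seed = 1)$beta, 2,
               tolerance = 1e-8)

  # 6 ratios near 2, 4 near 5 -> mode within 0.2 of 2 (grid-search oracle)
  set.seed(11)
  ratios <- c(rnorm(6, 2, 0.05), rnorm(4, 5, 0.05))
  be <- rep(0.2, 10)
  s <- make_summaries(be, ratios * be, se_outcome = rep(0.2, 10))
  mo <- mr_weighted_mode(s, n_boot = 150, seed = 3)
  expect_lt(abs(mo$beta - 2), 0.2)
  # independent coarse grid search over the weighted kernel density
  w <- be^2 / 0.2^2
  h <- 0.9 * min(sd(ratios), mad(ratios)) * 10^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 2000)
  dens <- vapply(grid, function(x0)
    sum(w * stats::dnorm((x0 - ratios) / h)), numeric(1))
  expect_lt(abs(mo$beta - grid[which.max(dens)]), 0.05)

  # doubling the bandwidth moves the estimate continuously
  mo2 <- mr_weighted_mode(s, bandwidth_factor = 1.05, n_boot = 150, seed = 3)
  expect_lt(abs(mo2$beta - mo$beta), 0.5)
})

test_that("RAPS reduces to IVW without exposure noise and matches grid search", {
  set.seed(12)
  s <- make_summaries(beta_exposure = runif(8, 0.05, 0.3),
                      beta_outcome = rnorm(8, 2, 0.8),
                      se_exposure = rep(0, 8),
                      se_outcome = runif(8, 0.5, 2))
  expect_equal(mr_raps(s)$beta, mr_ivw(s, "fixed")$beta, tolerance = 1e-8)

  # single SNP with exposure noise: verify against a fine 1-D grid search
  s1 <- make_summaries(0.2, 0.5, se_exposure = 0.05, se_outcome = 0.3)
  rp <- mr_raps(s1)
  grid <- seq(-10, 10, length.out = 400001)
  ll <- -0.5 * (0.5 - grid * 0.2)^2 / (0.3^2 + grid^2 * 0.05^2)
  expect_equal(rp$beta, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("multivariable MR matches the WLS oracle and nests univariable IVW", {
  mk_assoc <- function(beta, se = rep(0.5, length(beta))) {
    tibble::tibble(snp = sprintf("rs%05d", seq_along(beta)),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = beta, se = se, pval = 0.5, n = 1000)
  }
  set.seed(13)
  b1 <- runif(4, 0.05, 0.3)
  b2 <- runif(4, 0.02, 0.2)
  sy <- runif(4, 0.5, 2)
  bo <- 2 * b1 - 1.5 * b2 + rnorm(4, 0, 0.1)
  res <- mr_mvmr(mk_assoc(b1), mk_assoc(b2), mk_assoc(bo, sy))
  oracle <- lm(bo ~ 0 + b1 + b2, weights = 1 / sy^2)
  expect_equal(res$beta, unname(coef(oracle)), tolerance = 1e-10)

  # second exposure identically zero: first coefficient equals IVW
  res0 <- mr_mvmr(mk_assoc(b1), mk_assoc(rep(0, 4)), mk_assoc(bo, sy))
  s_uni <- make_summaries(b1, bo, se_outcome = sy)
  expect_equal(res0$beta[1], mr_ivw(s_uni, "fixed")$beta, tolerance = 1e-10)
  expect_true(is.na(res0$beta[2]))

  # collinear designs are rejected as conditionally weak
  expect_error(mr_mvmr(mk_assoc(b1), mk_assoc(2 * b1), mk_assoc(bo, sy)),
               class = "mrcost_error_rank")
})

test_that("SD-unit conversion is exact division", {
  expect_equal(sd_to_natural_units(9.2), 2)
  expect_equal(sd_to_natural_units(0), 0)
  expect_equal(sd_to_natural_units(4.6), 1)
  expect_error(sd_to_natural_units(1, sd = 0), class = "mrcost_error_arg")

  est <- mr_ivw(make_summaries(c(0.1, 0.2, 0.3), 2 * c(0.1, 0.2, 0.3)))
  conv <- sd_to_natural_units(est, sd = 2)
  expect_equal(conv$beta, est$beta / 2)
  expect_equal(conv$se, est$se / 2)
})

test_that("tidiers return well-formed tibbles", {
  s <- make_summaries(c(0.1, 0.2, 0.3), c(0.25, 0.38, 0.61))
  eg <- mr_egger(s)
  td <- tidy(eg)
  expect_equal(td$term, c("exposure", "(intercept)"))
  expect_equal(td$estimate[1], eg$beta)
  gl <- glance(eg)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_snps, 3L)

  all_est <- mr_all(s, methods = c("ivw", "egger", "raps"))
  expect_s3_class(all_est, "mr_estimates")
  expect_equal(nrow(all_est), 3L)
})
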