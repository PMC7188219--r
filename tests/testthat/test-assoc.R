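test_that("per-SNP regression matches the closed-form OLS oracle", {
  # toy data: dosages 0,1,2,1; trait 1.0,2.1,2.9,2.0 -> hand OLS slope
  g <- c(0, 1, 2, 1)
  y <- c(1.0, 2.1, 2.9, 2.0)
  slope_hand <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)

  panel <- tiny_panel(1)
  cohort <- tibble::tibble(id = as.character(1:4), exposure = y, cost = 0,
                           rs00001 = g)
  attr(cohort, "snp_ids") <- "rs00001"
  out <- snp_associations(cohort, "exposure")
  expect_equal(out$beta, slope_hand, tolerance = 1e-12)

  # against lm() as an independent fit, including covariates
  co <- simulate_cohort(tiny_panel(4, seed = 61), sim_params(), 500, seed = 62)
  out2 <- snp_associations(co, "exposure", covariates = c("sex", "age"))
  for (j in seq_len(4)) {
    fit <- lm(co$exposure ~ genotype_matrix(co)[, j] + co$sex + co$age)
    expect_equal(out2$beta[j], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(out2$se[j], unname(sqrt(diag(vcov(fit)))[2]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate inputs are handled: null trait and monomorphic SNPs", {
  co <- simulate_cohort(tiny_panel(3, seed = 71), sim_params(), 200, seed = 72)
  co$exposure <- rep(0, 200)
  out <- snp_associations(co, "exposure")
  expect_equal(out$beta, rep(0, 3))
  expect_true(all(out$pval > 0.999))

  co2 <- simulate_cohort(tiny_panel(3, seed = 73), sim_params(), 200, seed = 74)
  co2$rs00002 <- 1
  expect_message(out2 <- snp_associations(co2, "exposure"))
  expect_equal(attr(out2, "dropped"), "rs00002")
  expect_setequal(out2$snp, c("rs00001", "rs00003"))
})

test_that("harmonization flips swapped alleles and drops ambiguous SNPs", {
  ex <- dplyr::bind_rows(
    assoc_row("rs1", "A", "G", 0.3, 0.10),
    assoc_row("rs2", "A", "T", 0.50, 0.12),  # palindromic at 0.5
    assoc_row("rs3", "C", "G", 0.30, 0.15),  # palindromic, clear freq
    assoc_row("rs4", "A", "G", 0.25, 0.20)
  )
  ou <- dplyr::bind_rows(
    assoc_row("rs1", "G", "A", 0.7, 0.2),    # swapped -> flip
    assoc_row("rs2", "A", "T", 0.48, 0.3),
    assoc_row("rs3", "C", "G", 0.31, 0.4),
    assoc_row("rs4", "A", "C", 0.25, 0.5)    # mismatched -> triallelic
  )
  h <- harmonize_summaries(ex, ou)
  expect_equal(h$disposition,
               c("flipped", "dropped_palindromic", "kept",
                 "dropped_triallelic"))
  expect_equal(h$beta_outcome[1], -0.2)
  expect_equal(h$eaf_outcome[1], 0.3)
  expect_equal(h$beta_outcome[3], 0.4)

  # identical alleles and frequencies: everything kept, betas unchanged
  h2 <- harmonize_summaries(ex[c(1, 4), ], ex[c(1, 4), ])
  expect_true(all(h2$disposition == "kept"))
  expect_equal(h2$beta_outcome, ex$beta[c(1, 4)])
})

test_that("harmonization is involution-safe", {
  ex <- dplyr::bind_rows(
    assoc_row("rs1", "A", "G", 0.3, 0.10),
    assoc_row("rs3", "C", "G", 0.30, 0.15),
    assoc_row("rs4", "T", "C", 0.25, 0.20)
  )
  ou <- dplyr::bind_rows(
    assoc_row("rs1", "G", "A", 0.7, 0.2),
    assoc_row("rs3", "G", "C", 0.68, 0.4),
    assoc_row("rs4", "T", "C", 0.26, 0.5)
  )
  h1 <- harmonize_summaries(ex, ou)
  # rebuild the aligned outcome table and harmonize again: nothing changes
  ou2 <- tibble::tibble(
    snp = h1$snp, chrom = 1L, pos_bp = 1L,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_outcome, beta = h1$beta_outcome,
    se = h1$se_outcome, pval = h1$pval_outcome, n = h1$n_outcome
  )
  h2 <- harmonize_summaries(ex, ou2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
  expect_true(all(h2$disposition == "kept"))
})

test_that("duplicate snp ids are rejected", {
  ex <- dplyr::bind_rows(assoc_row("rs1", "A", "G", 0.3, 0.1),
                         assoc_row("rs1", "A", "G", 0.3, 0.1))
  expect_error(harmonize_summaries(ex, ex), class = "mrcost_error_dup")
})

test_that("LD clumping keeps the admissible best subset", {
  mk <- function(snp, chrom, pos, pval) {
    tibble::tibble(snp = snp, chrom = chrom, pos_bp = pos,
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = 0.1, se = 0.01, pval = pval, n = 1000)
  }
  assocs <- dplyr::bind_rows(
    mk("s1", 1, 1000, 1e-10), mk("s2", 1, 1500, 1e-9), mk("s3", 1, 2000, 1e-8)
  )
  ld <- diag(3)
  dimnames(ld) <- list(assocs$snp, assocs$snp)
  ld["s1", "s2"] <- ld["s2", "s1"] <- 0.5
  expect_equal(ld_clump(assocs, ld), c("s1", "s3"))

  # brute force: verify result is the greedy-admissible set over all subsets
  admissible <- function(keep) {
    if (length(keep) < 2) return(TRUE)
    for (a in keep) for (b in keep) {
      if (a != b && ld[a, b] >= 0.001 &&
          abs(assocs$pos_bp[assocs$snp == a] -
              assocs$pos_bp[assocs$snp == b]) <= 1e7) return(FALSE)
    }
    TRUE
  }
  expect_true(admissible(ld_clump(assocs, ld)))

  # all independent -> all kept
  ld0 <- diag(3); dimnames(ld0) <- dimnames(ld)
  expect_setequal(ld_clump(assocs, ld0), assocs$snp)

  # high correlation outside the window -> both kept
  assocs2 <- dplyr::bind_rows(mk("a", 1, 1, 1e-10), mk("b", 1, 2.5e10, 1e-9))
  ld2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_setequal(ld_clump(assocs2, ld2), c("a", "b"))

  # missing positions are rejected
  assocs3 <- assocs
  assocs3$pos_bp[2] <- NA
  expect_error(ld_clump(assocs3, ld), class = "mrcost_error_pos")
})

test_that("clumping output never violates the threshold/window rule", {
  set.seed(81)
  for (rep in 1:10) {
    J <- 12
    assocs <- tibble::tibble(
      snp = sprintf("s%02d", 1:J),
      chrom = sample(1:2, J, replace = TRUE),
      pos_bp = sample.int(2e7, J),
      effect_allele = "A", other_allele = "G", eaf = 0.3, beta = 0.1,
      se = 0.01, pval = runif(J, 1e-12, 1e-4), n = 1000
    )
    R <- matrix(runif(J * J), J)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    dimnames(R) <- list(assocs$snp, assocs$snp)
    kept <- ld_clump(assocs, R, r2_threshold = 0.3, window_kb = 5000)
    for (a in kept) for (b in kept) {
      if (a < b) {
        ia <- match(a, assocs$snp); ib <- match(b, assocs$snp)
        same_window <- assocs$chrom[ia] == assocs$chrom[ib] &&
          abs(assocs$pos_bp[ia] - assocs$pos_bp[ib]) <= 5e6
        expect_false(same_window && R[a, b] >= 0.3)
      }
    }
  }
})

test_that("allele scores are exact weighted dosage sums", {
  co <- simulate_cohort(tiny_panel(2, seed = 91), sim_params(), 50, seed = 92)
  w0 <- setNames(c(0, 0), c("rs00001", "rs00002"))
  expect_equal(allele_score(co, w0), rep(0, 50))

  co1 <- co[1, ]
  co1$rs00001 <- 2; co1$rs00002 <- 1
  expect_equal(allele_score(co1, setNames(c(0.1, 0.3), c("rs00001", "rs00002"))),
               0.5)

  expect_error(allele_score(co, setNames(0.1, "rs_absent")),
               class = "mrcost_error_arg")
  expect_error(allele_score(co, setNames(-0.1, "rs00001")),
               class = "mrcost_error_arg")
})

test_that("per-SD score weights recover the exposure SD as first-stage slope", {
  panel <- snp_panel(seed = 11)
  co <- simulate_cohort(panel, sim_params(), n = 50000, seed = 93)
  w <- panel$gamma / 4.6  # weights in SD units of the exposure
  score <- allele_score(co, setNames(w, panel$snp_id))
  slope <- coef(lm(co$exposure ~ score))[2]
  # theoretical slope is the exposure SD (4.6); allow Monte Carlo slack
  expect_lt(abs(slope - 4.6), 0.5)
})

test_that("instrument diagnostics: F statistic, R^2 and balance", {
  panel <- tiny_panel(6, seed = 95)
  co <- simulate_cohort(panel, sim_params(), n = 5000, seed = 96)
  score <- allele_score(co, panel[, c("snp_id", "gamma")])
  d <- instrument_diagnostics(co, score)
  # single-instrument F equals the squared first-stage t statistic
  fit <- summary(lm(co$exposure ~ score))
  expect_equal(d$f_statistic, fit$coefficients[2, "t value"]^2,
               tolerance = 1e-6)
  expect_true(d$r_squared >= 0 && d$r_squared <= 1)
  expect_true(all(d$score_covariate_pvals$pval >= 0 &
                    d$score_covariate_pvals$pval <= 1))

  # perfect instrument is flagged rather than reported as a finite F
  d2 <- instrument_diagnostics(co, co$exposure)
  expect_true(is.infinite(d2$f_statistic))
  expect_true(d2$perfect_instrument)
})

test_that("score-covariate balance p-values are uniform under the null", {
  panel <- tiny_panel(4, seed = 97)
  set.seed(42)
  pvals <- replicate(200, {
    co <- simulate_cohort(panel, sim_params(), n = 300)
    score <- allele_score(co, panel[, c("snp_id", "gamma")])
    d <- instrument_diagnostics(co, score, covariates = "pc1")
    d$score_covariate_pvals$pval
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.05)
})
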