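#' Per-SNP association scan
#'
#' Regresses a trait on each SNP dosage in turn (plus optional covariates,
#' partialled out by Frisch-Waugh residualisation, which reproduces the
#' multiple-regression coefficient exactly). Inference uses a two-sided
#' normal reference. Monomorphic (constant) genotype columns are excluded
#' with a message; their ids are attached as attribute `"dropped"`.
#'
#' @param cohort A cohort tibble.
#' @param trait Name of the trait column (e.g. `"exposure"` or `"cost"`).
#' @param covariates Character vector of covariate column names, or `NULL`.
#' @return A tibble of class `snp_assoc` with columns `snp`, `chrom`,
#'   `pos_bp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`.
#' @export
snp_associations <- function(cohort, trait = "exposure", covariates = NULL) {
  if (!trait %in% names(cohort)) {
    abort(paste0("trait `", trait, "` not found in cohort."),
          class = "mrcost_error_arg")
  }
  G <- genotype_matrix(cohort)
  y <- cohort[[trait]]
  n <- length(y)
  keep <- apply(G, 2L, function(g) length(unique(g)) > 1L)
  dropped <- colnames(G)[!keep]
  if (length(dropped)) {
    inform(paste0("excluding ", length(dropped),
                  " monomorphic SNP(s): ", paste(dropped, collapse = ", ")))
  }
  G <- G[, keep, drop = FALSE]
  eaf_obs <- colMeans(G) / 2

  k <- 0L
  if (!is.null(covariates) && length(covariates)) {
    Z <- cbind(1, as.matrix(cohort[, covariates, drop = FALSE]))
    qz <- qr(Z)
    y_r <- qr.resid(qz, y)
    G_r <- qr.resid(qz, G)
    k <- length(covariates)
  } else {
    y_r <- y - mean(y)
    G_r <- sweep(G, 2L, colMeans(G))
  }

  sgg <- colSums(G_r^2)
  beta <- colSums(G_r * y_r) / sgg
  rss <- sum(y_r^2) - 2 * beta * colSums(G_r * y_r) + beta^2 * sgg
  # algebraically rss_j = ssy - beta_j^2 * sgg_j; keep the stable form
  rss <- pmax(sum(y_r^2) - beta^2 * sgg, 0)
  df <- n - 2L - k
  se <- sqrt(rss / df / sgg)
  z <- ifelse(se > 0, beta / se, 0)
  pv <- ifelse(se > 0, two_sided_p(z), 1)

  panel <- cohort_panel(cohort)
  snp <- colnames(G)
  meta <- if (!is.null(panel)) panel[match(snp, panel$snp_id), ] else NULL
  out <- tibble(
    snp = snp,
    chrom = if (!is.null(meta)) meta$chrom else NA_integer_,
    pos_bp = if (!is.null(meta)) meta$pos_bp else NA_integer_,
    effect_allele = if (!is.null(meta)) meta$effect_allele else NA_character_,
    other_allele = if (!is.null(meta)) meta$other_allele else NA_character_,
    eaf = eaf_obs,
    beta = unname(beta),
    se = unname(se),
    pval = unname(pv),
    n = n
  )
  attr(out, "dropped") <- dropped
  class(out) <- c("snp_assoc", class(tibble()))
  out
}

#' Two-sample summary statistics from disjoint cohorts
#'
#' Estimates per-SNP exposure associations in one cohort and per-SNP outcome
#' (cost) associations in another, and returns them as aligned summary pairs
#' ready for the summary-data MR estimators. If the two cohorts share
#' individual identifiers a warning is raised: sample overlap biases IV
#' estimates toward the confounded observational estimate.
#'
#' @param cohort_exposure,cohort_outcome Cohort tibbles sharing a SNP panel.
#' @param covariates Covariate names adjusted for in both scans.
#' @return An `mr_summaries` tibble with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf_exposure`, `eaf_outcome`, `beta_exposure`,
#'   `se_exposure`, `pval_exposure`, `beta_outcome`, `se_outcome`,
#'   `pval_outcome`, `n_exposure`, `n_outcome`, `disposition`.
#' @export
two_sample_summaries <- function(cohort_exposure, cohort_outcome,
                                 covariates = NULL) {
  if (length(intersect(cohort_exposure$id, cohort_outcome$id))) {
    warn(paste0("exposure and outcome cohorts share individuals; ",
                "one-sample overlap biases estimates toward the ",
                "non-IV (confounded) estimate."),
         class = "mrcost_warning_overlap")
  }
  ax <- snp_associations(cohort_exposure, "exposure", covariates)
  ay <- snp_associations(cohort_outcome, "cost", covariates)
  shared <- intersect(ax$snp, ay$snp)
  ax <- ax[match(shared, ax$snp), ]
  ay <- ay[match(shared, ay$snp), ]
  out <- tibble(
    snp = shared,
    effect_allele = ax$effect_allele,
    other_allele = ax$other_allele,
    eaf_exposure = ax$eaf,
    eaf_outcome = ay$eaf,
    beta_exposure = ax$beta,
    se_exposure = ax$se,
    pval_exposure = ax$pval,
    beta_outcome = ay$beta,
    se_outcome = ay$se,
    pval_outcome = ay$pval,
    n_exposure = ax$n,
    n_outcome = ay$n,
    disposition = "kept"
  )
  new_mr_summaries(out)
}

new_mr_summaries <- function(df) {
  class(df) <- unique(c("mr_summaries", class(tibble())))
  df
}

# rows usable by estimators
kept_summaries <- function(summaries) {
  if ("disposition" %in% names(summaries)) {
    summaries <- summaries[summaries$disposition %in% c("kept", "flipped"), ]
  }
  if (!nrow(summaries)) {
    abort("no SNPs available after harmonization/filtering.",
          class = "mrcost_error_empty")
  }
  summaries
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two per-SNP association tables onto a common effect allele. When
#' the effect/other alleles are swapped between sources the outcome effect is
#' sign-flipped and its frequency complemented. Palindromic SNPs (A/T, C/G)
#' cannot be aligned from alleles alone and are reconciled by allele
#' frequency: kept only if both frequencies are outside 0.5 +/-
#' `palindromic_window`; if they fall on opposite sides of 0.5 the outcome
#' effect is flipped. SNPs with irreconcilable alleles are dropped as
#' triallelic. Every SNP's disposition is recorded.
#'
#' @param exposure,outcome `snp_assoc` tibbles (columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`).
#' @param palindromic_window Half-width of the ambiguous frequency band
#'   around 0.5 (default 0.08: drop if either frequency is within
#'   [0.42, 0.58]).
#' @return An `mr_summaries` tibble as in [two_sample_summaries()], including
#'   dropped SNPs with their `disposition` (`"kept"`, `"flipped"`,
#'   `"dropped_palindromic"`, `"dropped_triallelic"`).
#' @export
harmonize_summaries <- function(exposure, outcome, palindromic_window = 0.08) {
  for (nm in list(list(exposure, "exposure"), list(outcome, "outcome"))) {
    if (anyDuplicated(nm[[1]]$snp)) {
      abort(paste0("duplicate snp ids in ", nm[[2]], " associations."),
            class = "mrcost_error_dup")
    }
  }
  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  n <- length(shared)
  disposition <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele

  for (i in seq_len(n)) {
    if (pal[i]) {
      if (!(same[i] || swapped[i])) {
        disposition[i] <- "dropped_triallelic"
        next
      }
      in_window <- function(f) abs(f - 0.5) <= palindromic_window
      if (in_window(ex$eaf[i]) || in_window(eaf_out[i])) {
        disposition[i] <- "dropped_palindromic"
      } else if (sign(ex$eaf[i] - 0.5) == sign(eaf_out[i] - 0.5)) {
        disposition[i] <- "kept"
      } else {
        disposition[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else if (same[i]) {
      disposition[i] <- "kept"
    } else if (swapped[i]) {
      disposition[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else {
      disposition[i] <- "dropped_triallelic"
    }
  }

  out <- tibble(
    snp = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    eaf_exposure = ex$eaf,
    eaf_outcome = eaf_out,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    pval_exposure = ex$pval,
    beta_outcome = beta_out,
    se_outcome = ou$se,
    pval_outcome = ou$pval,
    n_exposure = ex$n,
    n_outcome = ou$n,
    disposition = disposition
  )
  new_mr_summaries(out)
}

#' Greedy LD clumping
#'
#' Retains an approximately independent SNP subset: SNPs are visited in order
#' of ascending p-value (ties broken by `snp` id) and dropped if they lie
#' within `window_kb` of an already-kept SNP on the same chromosome with
#' squared correlation at or above `r2_threshold`.
#'
#' @param assocs A `snp_assoc` tibble with `snp`, `pval` and, unless
#'   `positions` is supplied, `chrom`/`pos_bp` columns.
#' @param ld_r2 Symmetric matrix of squared allelic correlations with unit
#'   diagonal, dimnames matching `snp`.
#' @param positions Optional tibble (`snp`, `chrom`, `pos_bp`) overriding the
#'   positions in `assocs`.
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @param window_kb Physical window in kilobases (default 10,000).
#' @return Character vector of retained snp ids.
#' @export
ld_clump <- function(assocs, ld_r2, positions = NULL,
                     r2_threshold = 0.001, window_kb = 10000) {
  if (!is.null(positions)) {
    idx <- match(assocs$snp, positions$snp)
    chrom <- positions$chrom[idx]
    pos <- positions$pos_bp[idx]
  } else {
    chrom <- assocs$chrom
    pos <- assocs$pos_bp
  }
  if (anyNA(chrom) || anyNA(pos)) {
    abort("missing position for one or more SNPs.", class = "mrcost_error_pos")
  }
  if (!isTRUE(all.equal(ld_r2, t(ld_r2))) ||
      !isTRUE(all.equal(unname(diag(ld_r2)), rep(1, nrow(ld_r2))))) {
    abort("`ld_r2` must be symmetric with unit diagonal.",
          class = "mrcost_error_ld")
  }
  ord <- order(assocs$pval, assocs$snp)
  kept <- character(0)
  for (i in ord) {
    s <- assocs$snp[i]
    conflict <- FALSE
    for (k in kept) {
      j <- match(k, assocs$snp)
      if (chrom[i] == chrom[j] &&
          abs(pos[i] - pos[j]) <= window_kb * 1000 &&
          ld_r2[s, k] >= r2_threshold) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, s)
  }
  kept
}

#' Weighted allele score
#'
#' Computes \eqn{score_i = \sum_j w_j \, dosage_{ij}} with weights oriented to
#' the exposure-increasing allele (all weights must be non-negative).
#'
#' @param cohort A cohort tibble.
#' @param weights Named numeric vector of per-SNP weights (names are snp ids),
#'   or a tibble with columns `snp` and `weight` (a `snp_panel`'s `snp_id` /
#'   `gamma` columns also work).
#' @return Numeric score vector, one element per individual.
#' @export
allele_score <- function(cohort, weights) {
  if (is.data.frame(weights)) {
    nm <- if ("snp" %in% names(weights)) weights$snp else weights$snp_id
    w <- if ("weight" %in% names(weights)) weights$weight else weights$gamma
    names(w) <- nm
    weights <- w
  }
  if (is.null(names(weights))) {
    abort("`weights` must be named by snp id.", class = "mrcost_error_arg")
  }
  if (any(weights < 0)) {
    abort("weights must be oriented to the exposure-increasing allele (>= 0).",
          class = "mrcost_error_arg")
  }
  missing <- setdiff(names(weights), names(cohort))
  if (length(missing)) {
    abort(paste0("weight given for SNP(s) absent from the cohort: ",
                 paste(missing, collapse = ", ")),
          class = "mrcost_error_arg")
  }
  G <- as.matrix(cohort[, names(weights), drop = FALSE])
  drop(G %*% unname(weights))
}

#' Instrument-strength and balance diagnostics
#'
#' First-stage F statistic of the exposure on the allele score, variance in
#' the exposure explained by the full SNP set, and score-versus-covariate
#' balance tests (the score should be independent of non-genetic covariates
#' if instrument assignment is effectively random).
#'
#' @param cohort A cohort tibble.
#' @param score Allele-score vector from [allele_score()].
#' @param covariates Covariate names for the balance table (default: all of
#'   `sex`, `age`, `deprivation`, `pc1`-`pc3` that are present).
#' @return A list of class `instrument_diagnostics` with `f_statistic`
#'   (`Inf` and `perfect_instrument = TRUE` when the score reproduces the
#'   exposure exactly), `r_squared`, `score_covariate_pvals` (tibble), `n`.
#' @export
instrument_diagnostics <- function(cohort, score, covariates = NULL) {
  if (sd(score) == 0) {
    abort("score is constant.", class = "mrcost_error_arg")
  }
  covariates <- covariates %||%
    intersect(c("sex", "age", "deprivation", "pc1", "pc2", "pc3"),
              names(cohort))
  n <- nrow(cohort)
  G <- genotype_matrix(cohort)
  if (n <= ncol(G) + 2L) {
    abort("sample size must exceed the number of regressors.",
          class = "mrcost_error_arg")
  }
  x <- cohort$exposure

  fs <- simple_slope(x, score)
  perfect <- fs$se == 0 || isTRUE(all.equal(cor(x, score)^2, 1))
  f_stat <- if (perfect) Inf else (fs$beta / fs$se)^2

  # R^2 of exposure on the full SNP set
  Xg <- cbind(1, G)
  qg <- qr(Xg)
  r2 <- 1 - sum(qr.resid(qg, x)^2) / sum((x - mean(x))^2)

  bal <- purrr::map_dfr(covariates, function(cv) {
    sl <- simple_slope(score, as.numeric(cohort[[cv]]))
    tibble(covariate = cv, estimate = sl$beta, pval = sl$pval)
  })

  structure(list(
    f_statistic = f_stat,
    perfect_instrument = perfect,
    r_squared = r2,
    score_covariate_pvals = bal,
    n = n
  ), class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat("Instrument diagnostics\n")
  cat(sprintf("  first-stage F: %s\n",
              if (is.infinite(x$f_statistic)) "Inf (perfect instrument)"
              else format(x$f_statistic, digits = 4)))
  cat(sprintf("  R^2 (exposure ~ SNPs): %.4f\n", x$r_squared))
  cat(sprintf("  n: %d\n", x$n))
  print(x$score_covariate_pvals)
  invisible(x)
}
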