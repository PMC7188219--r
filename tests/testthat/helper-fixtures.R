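# Small deterministic fixtures shared across test files.

tiny_panel <- function(n_snps = 5, seed = 101, ...) {
  snp_panel(n_snps = n_snps, seed = seed, ...)
}

# hand-built association table for harmonization tests
assoc_row <- function(snp, ea, oa, eaf, beta, se = 0.1, pval = 1e-9, n = 1000) {
  tibble::tibble(snp = snp, chrom = 1L, pos_bp = 1L,
                 effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pval = pval, n = n)
}

# summaries tibble straight from numbers (already harmonized)
make_summaries <- function(beta_exposure, beta_outcome,
                           se_exposure = rep(0.02, length(beta_exposure)),
                           se_outcome = rep(1, length(beta_exposure))) {
  J <- length(beta_exposure)
  tibble::tibble(
    snp = sprintf("rs%05d", seq_len(J)),
    effect_allele = "A", other_allele = "G",
    eaf_exposure = 0.3, eaf_outcome = 0.3,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    pval_exposure = 0, beta_outcome = beta_outcome,
    se_outcome = se_outcome, pval_outcome = 0,
    n_exposure = 1000L, n_outcome = 1000L,
    disposition = "kept"
  )
}

# brute-force weighted median: fine grid minimising weighted absolute
# deviation is avoided in favour of the cumulative-weight definition applied
# directly, computed independently of the package implementation
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ws <- w[ord] / sum(w)
  cum <- cumsum(ws) - ws / 2
  if (0.5 <= cum[1]) return(r[1])
  if (0.5 >= cum[length(r)]) return(r[length(r)])
  stats::approx(cum, r, xout = 0.5)$y
}
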