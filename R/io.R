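assoc_header <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

#' Write per-SNP summary statistics as tab-separated text
#'
#' Fixed header: `snp, chr, pos, effect_allele, other_allele, eaf, beta, se,
#' pval, n`.
#'
#' @param assocs A `snp_assoc` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_assoc <- function(assocs, path) {
  out <- tibble(
    snp = assocs$snp, chr = assocs$chrom, pos = assocs$pos_bp,
    effect_allele = assocs$effect_allele, other_allele = assocs$other_allele,
    eaf = assocs$eaf, beta = assocs$beta, se = assocs$se,
    pval = assocs$pval, n = assocs$n
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-SNP summary statistics
#'
#' @param path A tab-separated file written by [write_snp_assoc()] (or any
#'   file with the same header).
#' @return A `snp_assoc` tibble.
#' @export
read_snp_assoc <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(assoc_header %in% names(df))) {
    abort(paste0("summary-statistics file must have columns: ",
                 paste(assoc_header, collapse = ", ")),
          class = "mrcost_error_io")
  }
  out <- tibble(
    snp = as.character(df$snp), chrom = df$chr, pos_bp = df$pos,
    effect_allele = as.character(df$effect_allele),
    other_allele = as.character(df$other_allele),
    eaf = df$eaf, beta = df$beta, se = df$se, pval = df$pval, n = df$n
  )
  class(out) <- c("snp_assoc", class(tibble()))
  out
}

#' Write a cohort table with a sidecar metadata file
#'
#' One row per individual, genotype columns named by snp id; a JSON sidecar
#' (`<path>.meta.json`) records the SNP panel so the cohort can be
#' round-tripped.
#'
#' @param cohort An `mr_cohort` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panel <- cohort_panel(cohort)
  meta <- list(snp_ids = attr(cohort, "snp_ids"), panel = panel)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path TSV path (the `<path>.meta.json` sidecar must sit alongside).
#' @return An `mr_cohort` tibble.
#' @export
read_cohort <- function(path) {
  df <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(readLines(meta_path))
    panel <- as_tibble(meta$panel)
    out <- new_mr_cohort(df, panel)
  } else {
    out <- df
    attr(out, "snp_ids") <- grep("^rs", names(df), value = TRUE)
    class(out) <- c("mr_cohort", class(tibble()))
  }
  out
}
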