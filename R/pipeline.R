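scenario_registry <- function() {
  list(
    "no-pleiotropy" = list(pleiotropy = "none"),
    "balanced-pleiotropy" = list(pleiotropy = "balanced"),
    "directional-pleiotropy" = list(pleiotropy = "directional",
                                    alpha_mean = 15, alpha_sd = 7.5,
                                    prop_invalid = 1),
    "invalid-40pct" = list(pleiotropy = "directional",
                           alpha_mean = 25, alpha_sd = 5,
                           prop_invalid = 0.4),
    "confounder-pleiotropy" = list(pleiotropy = "confounder")
  )
}

#' Pipeline configuration
#'
#' Validated bundle of settings for [run_pipeline()]. Unknown keys are
#' rejected rather than ignored.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_exposure,n_outcome Sample sizes of the two simulated cohorts.
#' @param n_snps Number of instrument SNPs.
#' @param scenario Name of a registered pleiotropy scenario (one of
#'   `"no-pleiotropy"`, `"balanced-pleiotropy"`, `"directional-pleiotropy"`,
#'   `"invalid-40pct"`, `"confounder-pleiotropy"`).
#' @param beta True causal effect (pounds per exposure unit per person-year).
#' @param estimators Estimator labels passed to [mr_all()].
#' @param k_strata Number of residual-exposure strata for the non-linear
#'   analysis.
#' @param n_boot Bootstrap replicates for median/mode estimators.
#' @param run_nonlinear Run the residual-stratification analysis (needs
#'   `n_outcome >= 10 * k_strata`).
#' @param population,delta_exposure Inputs of the policy projection.
#' @param output_dir Directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param ... Rejected; present so misspelled keys fail loudly.
#' @return A named list of class `mr_config`.
#' @export
mr_config <- function(seed = 1, n_exposure = 20000, n_outcome = 20000,
                      n_snps = 79, scenario = "no-pleiotropy", beta = 20,
                      estimators = c("ivw", "egger", "weighted_median",
                                     "weighted_mode", "raps"),
                      k_strata = 100, n_boot = 1000, run_nonlinear = TRUE,
                      population = 5e7, delta_exposure = 1,
                      output_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(paste0("unknown configuration key(s): ",
                 paste(names(extra), collapse = ", ")),
          class = "mrcost_error_config")
  }
  if (!scenario %in% names(scenario_registry())) {
    abort(paste0("`scenario` must name a registered preset: ",
                 paste(names(scenario_registry()), collapse = ", ")),
          class = "mrcost_error_config")
  }
  counts <- c(seed = seed, n_exposure = n_exposure, n_outcome = n_outcome,
              n_snps = n_snps, k_strata = k_strata, n_boot = n_boot)
  if (!all(is.finite(counts)) || any(counts[-1] <= 0)) {
    abort("all counts must be positive.", class = "mrcost_error_config")
  }
  structure(list(
    seed = as.integer(seed), n_exposure = n_exposure, n_outcome = n_outcome,
    n_snps = n_snps, scenario = scenario, beta = beta,
    estimators = estimators, k_strata = k_strata, n_boot = n_boot,
    run_nonlinear = run_nonlinear, population = population,
    delta_exposure = delta_exposure, output_dir = output_dir
  ), class = "mr_config")
}

#' Run the full analysis pipeline
#'
#' Simulates the two-sample cohorts for the configured scenario, builds the
#' harmonized summary statistics, runs the requested estimators, the
#' instrument diagnostics, the conventional comparators, optionally the
#' non-linear (LACE) analysis, and a policy projection based on the
#' penalized-weighted-median estimate. With `output_dir` set, writes the
#' tidy TSV tables, the forest/scatter plot data, a versioned JSON summary
#' and a structured log; the whole bundle is reproducible bit-for-bit from
#' (config, seed).
#'
#' @param config An `mr_config` (or a plain named list with the same keys).
#' @return A list of class `mr_report`: `config`, `panel`, `summaries`,
#'   `estimates`, `conventional`, `diagnostics`, `nonlinear` (or `NULL`),
#'   `policy`, `timings`.
#' @export
run_pipeline <- function(config = mr_config()) {
  if (!inherits(config, "mr_config")) config <- do.call(mr_config, config)
  stage_times <- numeric(0)
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  set.seed(config$seed)
  scen <- scenario_registry()[[config$scenario]]
  panel <- tick("panel", do.call(snp_panel, c(list(n_snps = config$n_snps), scen)))
  params <- sim_params(beta = config$beta)

  sims <- tick("simulate", simulate_two_sample(
    panel, params, config$n_exposure, config$n_outcome))
  summaries <- tick("summaries", two_sample_summaries(
    sims$exposure, sims$outcome))

  estimates <- tick("estimate", mr_all(
    summaries, methods = config$estimators, n_boot = config$n_boot))

  score <- allele_score(sims$outcome, panel[, c("snp_id", "gamma")])
  diagnostics <- tick("diagnostics", instrument_diagnostics(
    sims$outcome, score))
  conventional <- tick("conventional", conventional_estimates(sims$outcome))

  nonlinear <- NULL
  if (isTRUE(config$run_nonlinear) &&
      config$n_outcome >= 10 * config$k_strata) {
    nonlinear <- tick("nonlinear", nonlinearity_tests(
      stratify_lace(sims$outcome, score, K = config$k_strata)))
  }

  median_row <- estimates[grepl("median", estimates$method, ignore.case = TRUE), ]
  policy_beta <- if (nrow(median_row)) median_row$beta[1] else estimates$beta[1]
  policy <- policy_cost_projection(config$population, config$delta_exposure,
                                   policy_beta)

  report <- structure(list(
    config = config, panel = panel, summaries = summaries,
    estimates = estimates, conventional = conventional,
    diagnostics = diagnostics, nonlinear = nonlinear, policy = policy,
    timings = stage_times
  ), class = "mr_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

report_json <- function(report) {
  nl <- report$nonlinear
  jsonlite::toJSON(list(
    schema_version = "1.0",
    config = unclass(report$config)[setdiff(names(report$config), "output_dir")],
    estimates = report$estimates,
    conventional = report$conventional,
    diagnostics = list(
      f_statistic = report$diagnostics$f_statistic,
      r_squared = report$diagnostics$r_squared
    ),
    nonlinear = if (!is.null(nl)) list(
      fracpoly_d1_vs_linear_pval = nl$fracpoly_d1_vs_linear_pval,
      fracpoly_d2_vs_d1_pval = nl$fracpoly_d2_vs_d1_pval,
      quadratic_pval = nl$quadratic_pval,
      trend_pval = nl$trend_pval,
      first_stage_heterogeneity_pval = nl$first_stage_heterogeneity_pval
    ),
    policy = report$policy
  ), auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_ <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv_(report$summaries, "summaries.tsv")
  write_tsv_(report$estimates, "estimates.tsv")
  write_tsv_(forest_table(report$summaries, report$estimates), "forest.tsv")
  sc <- scatter_table(report$summaries, report$estimates)
  write_tsv_(sc$points, "scatter_points.tsv")
  write_tsv_(sc$lines, "scatter_lines.tsv")
  writeLines(report_json(report), file.path(dir, "summary.json"))
  log <- sprintf("stage=%s elapsed=%.3f seed=%d config_hash=%s",
                 names(report$timings), unlist(report$timings),
                 report$config$seed, rlang::hash(unclass(report$config)))
  writeLines(log, file.path(dir, "run.log"))
  invisible(report)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR pipeline report (scenario:", x$config$scenario, ")\n\n")
  print(x$estimates)
  cat("\nPolicy projection:", format(x$policy$total_cost, big.mark = ","),
      "pounds/year\n")
  invisible(x)
}

#' Forest-plot data table
#'
#' Per-SNP ratio estimates with 95\% confidence intervals (half-width
#' 1.96 se), ordered by effect size, followed by one summary row per
#' estimator.
#'
#' @param summaries An `mr_summaries` tibble.
#' @param estimates An `mr_estimates` tibble from [mr_all()] (optional).
#' @return A tibble with `label`, `type` (`"snp"`/`"summary"`), `estimate`,
#'   `lo`, `hi`.
#' @export
forest_table <- function(summaries, estimates = NULL) {
  ratios <- wald_ratios(summaries)
  snp_rows <- tibble(
    label = ratios$snp, type = "snp", estimate = unname(ratios$ratio),
    lo = ratios$ratio - 1.96 * ratios$se_ratio,
    hi = ratios$ratio + 1.96 * ratios$se_ratio
  )
  snp_rows <- snp_rows[order(snp_rows$estimate), ]
  if (!is.null(estimates)) {
    snp_rows <- dplyr::bind_rows(snp_rows, tibble(
      label = paste("All -", estimates$method), type = "summary",
      estimate = estimates$beta,
      lo = estimates$beta - 1.96 * estimates$se,
      hi = estimates$beta + 1.96 * estimates$se
    ))
  }
  snp_rows
}

#' Scatter-plot data table
#'
#' Per-SNP (exposure association, outcome association) pairs with 95\%
#' confidence intervals, plus the fitted line of each estimator (slope, and
#' intercept where the method has one).
#'
#' @inheritParams forest_table
#' @return A list of two tibbles: `points` and `lines`.
#' @export
scatter_table <- function(summaries, estimates = NULL) {
  s <- kept_summaries(summaries)
  points <- tibble(
    snp = s$snp,
    beta_exposure = s$beta_exposure,
    x_lo = s$beta_exposure - 1.96 * s$se_exposure,
    x_hi = s$beta_exposure + 1.96 * s$se_exposure,
    beta_outcome = s$beta_outcome,
    y_lo = s$beta_outcome - 1.96 * s$se_outcome,
    y_hi = s$beta_outcome + 1.96 * s$se_outcome
  )
  lines <- if (!is.null(estimates)) {
    tibble(method = estimates$method, slope = estimates$beta,
           intercept = ifelse(is.na(estimates$intercept), 0,
                              estimates$intercept))
  } else {
    tibble(method = character(), slope = numeric(), intercept = numeric())
  }
  list(points = points, lines = lines)
}
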