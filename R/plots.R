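#' Scatter plot of SNP-outcome against SNP-exposure associations
#'
#' Each point is one instrument with 95\% confidence bars on both axes;
#' each line is one estimator's fitted causal slope (the MR-Egger line has
#' its pleiotropy intercept).
#'
#' @param summaries An `mr_summaries` tibble.
#' @param estimates An `mr_estimates` tibble from [mr_all()] (optional).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(summaries, estimates = NULL) {
  sc <- scatter_table(summaries, estimates)
  p <- ggplot2::ggplot(sc$points,
                       ggplot2::aes(x = .data$beta_exposure,
                                    y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y_lo, ymax = .data$y_hi),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$x_lo, xmax = .data$x_hi),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP-exposure association (kg/m² per allele)",
                  y = "SNP-outcome association (£/person-year per allele)")
  if (nrow(sc$lines)) {
    p <- p + ggplot2::geom_abline(
      data = sc$lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)
    )
  }
  p
}

#' Forest plot of per-SNP ratio estimates
#'
#' SNPs ordered by effect size with the estimator summaries below, the
#' layout conventional for instrument-level MR displays.
#'
#' @inheritParams plot_mr_scatter
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(summaries, estimates = NULL) {
  ft <- forest_table(summaries, estimates)
  ft$label <- factor(ft$label, levels = rev(ft$label))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$estimate, y = .data$label,
                                   colour = .data$type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0) +
    ggplot2::geom_point() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "Causal estimate (£ per exposure unit)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot local average causal effects across the exposure distribution
#'
#' @param object An `mr_lace` tibble from [stratify_lace()].
#' @param ... Unused.
#' @return A ggplot object with per-stratum LACE and 95\% intervals against
#'   stratum mean exposure.
#' @method autoplot mr_lace
#' @export
autoplot.mr_lace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_exposure,
                                       y = .data$lace)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lace - 1.96 * .data$se,
                                          ymax = .data$lace + 1.96 * .data$se),
                             fatten = 1.5, colour = "grey40") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Stratum mean exposure (kg/m²)",
                  y = "Local average causal effect (£ per unit)")
}

#' @method autoplot mr_summaries
#' @export
autoplot.mr_summaries <- function(object, ...) plot_mr_scatter(object, ...)

#' @importFrom rlang .data
NULL
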