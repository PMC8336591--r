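#' Precision/recall cross plot for a benchmark run
#'
#' One panel per (cohort size, coordination proportion) configuration; for
#' each method a cross centred at the per-replicate median recall (x) and
#' precision (y), with arms spanning the lower to upper quartiles.
#'
#' @param object An `inter_benchmark` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.inter_benchmark <- function(object, ...) {
  s <- summarize_benchmark(object)
  s$size_lab <- factor(paste0(s$cohort_size, "vs", s$cohort_size),
                       levels = unique(paste0(sort(unique(s$cohort_size)),
                                              "vs",
                                              sort(unique(s$cohort_size)))))
  s$prop_lab <- paste0("coordination ", s$prop_coordinated)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$recall_median,
                                  y = .data$precision_median,
                                  colour = .data$method)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$precision_q1,
                                        ymax = .data$precision_q3),
                           width = 0.02) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$recall_q1,
                                         xmax = .data$recall_q3),
                            height = 0.02) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$prop_lab),
                        cols = ggplot2::vars(.data$size_lab)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall (median, quartile arms)",
                  y = "precision (median, quartile arms)",
                  colour = "method") +
    ggplot2::theme_bw()
}

#' Mixture-fit diagnostic plot
#'
#' Histogram of |log2FC| overlaid with the two fitted Gaussian components
#' scaled by their mixing proportions.
#'
#' @param fit A `mixenrich_fit`.
#' @param values The |log2FC| vector the fit was computed on.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_mixture <- function(fit, values, bins = 80) {
  df <- tibble::tibble(x = values)
  grid <- seq(0, max(values), length.out = 400)
  comp <- tibble::tibble(
    x = rep(grid, 2),
    density = c(fit$mix_props[1] * stats::dnorm(grid, fit$means[1], fit$sds[1]),
                fit$mix_props[2] * stats::dnorm(grid, fit$means[2], fit$sds[2])),
    component = rep(c("null", "de"), each = length(grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "|log2 fold change|", y = "density") +
    ggplot2::theme_bw()
}
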