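# ggplot2 figures for the screen results.

#' Scatter plot of log2 aggregate ratios with the screen cutoff line
#'
#' One point per treatment in run order; the dashed line is the 2-SD
#' cutoff below which aggregation counts as suppressed. Dual hits and
#' suppressors are coloured by classification.
#'
#' @param object A `hit_table` (from [call_hits()] or `run_screen()$hits`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hit_table <- function(object, ...) {
  threshold <- attr(object, "threshold")
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$log2_ratio), ]
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$log2_ratio,
                                   colour = .data$classification)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold$cutoff, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "treatment",
      y = expression(log[2] ~ "aggregate ratio (treated / vehicle)"),
      colour = NULL,
      title = "Aggregation suppression across the screen",
      subtitle = sprintf("dashed line: mean - %g sd = %.3f",
                         threshold$multiplier, threshold$cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Density plot of an area-bin mixture model over its data
#'
#' @param object An `area_bin_model`.
#' @param log2_areas Optional data to underlay as a histogram.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.area_bin_model <- function(object, log2_areas = NULL, ...) {
  grid <- seq(object$means[1] - 4 * object$sds[1],
              object$means[3] + 4 * object$sds[3], length.out = 400)
  comp <- purrr::map_dfr(seq_len(3), function(j) {
    tibble::tibble(
      bin = AREA_BINS[j], x = grid,
      density = object$weights[j] * dnorm(grid, object$means[j],
                                          object$sds[j])
    )
  })
  p <- ggplot2::ggplot()
  if (!is.null(log2_areas)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = log2_areas),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey85", colour = "grey70")
  }
  p +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$bin)) +
    ggplot2::labs(x = expression(log[2] ~ "neuromere area (" * mu * m^2 * ")"),
                  y = "density", colour = "bin",
                  title = "Three-bin Gaussian mixture of neuromere areas") +
    ggplot2::theme_minimal()
}

#' Morphology reversion plot: combined p-value per suppressed treatment
#'
#' @param hits A `hit_table`.
#' @param alpha Significance line (default the table's alpha attribute).
#' @return A ggplot object.
#' @export
plot_morphology_reversion <- function(hits, alpha = NULL) {
  stopifnot(inherits(hits, "hit_table"))
  alpha <- alpha %||% attr(hits, "alpha") %||% 0.05
  df <- tibble::as_tibble(hits)
  df <- df[df$aggregation_suppressed %in% TRUE, ]
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                   y = .data$morph_combined_p,
                                   colour = .data$classification)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "suppressed treatment",
                  y = "Fisher-combined morphology p",
                  colour = NULL,
                  title = "Morphology reversion among aggregation suppressors") +
    ggplot2::theme_minimal()
}
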