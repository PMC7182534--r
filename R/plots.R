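#' Plot a tile methylation distribution
#'
#' Histogram of regional methylation over tiles with data; the left-shift
#' of a hypomethylated methylome shows up directly.
#'
#' @param object A `"meth_distribution"` from
#'   [genome_methylation_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_distribution <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2, y = .data$count
  )) +
    ggplot2::geom_col(width = h$bin_end[1] - h$bin_start[1],
                      fill = "grey35") +
    ggplot2::labs(x = "Tile methylation", y = "Tiles") +
    ggplot2::theme_minimal()
}

#' Plot a depletion resampling result
#'
#' Histogram of DMR counts across background draws with the observed query
#' count marked; depletion appears as the observed line falling in (or
#' below) the left tail.
#'
#' @param object A `"depletion_result"` from [resample_depletion()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depletion_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n_dmr)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$observed_dmr,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "DMRs per background draw", y = "Draws",
      title = sprintf("Observed %d DMRs; empirical p = %.3g",
                      object$observed_dmr, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot methylation by annotation class and condition
#'
#' Median and interquartile range per class and condition, the summary
#' behind per-annotation violin displays.
#'
#' @param object An `"annotation_profile"` from
#'   [annotation_methylation_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.annotation_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(
    x = .data$klass, y = .data$median, ymin = .data$first_quartile,
    ymax = .data$third_quartile, colour = .data$condition
  )) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Annotation class", y = "Tile methylation",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Scatter of expression change against methylation difference
#'
#' One panel per annotation class: per-annotation methylation difference
#' (reference minus test) against the proximal gene's log2 fold-change.
#'
#' @param rows Integration rows from [integrate_expression_methylation()].
#' @return A ggplot.
#' @export
plot_meth_expression <- function(rows) {
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$delta_meth, y = .data$logfc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~klass) +
    ggplot2::labs(x = "Methylation difference (reference - test)",
                  y = "Expression log2 fold-change") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
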