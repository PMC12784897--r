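# ggplot2 displays for the main result types.

#' Plot a distance-decay fit
#'
#' Scatter of pairwise dissimilarity against the pairwise distance, with
#' the fitted OLS line.
#'
#' @param object A `decay_fit` from [distance_decay()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$distance, y = .data$beta)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = paste0(object$predictor, " distance"),
      y = paste0(object$level, " beta_", object$component),
      title = sprintf("Distance decay (adj R² = %.2f, p = %.3g)",
                      object$adj_r2, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a smooth trend along the dam-distance gradient
#'
#' @param object A `trend_fit` from [smooth_trend()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_fit <- function(object, ...) {
  df <- object$fitted[order(object$fitted$x), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue",
                       linewidth = 0.8) +
    ggplot2::labs(
      x = "distance from dam (km)", y = "response",
      title = sprintf("%s (DE = %.1f%%, p = %.3g)",
                      if (object$smooth) "GAM trend" else "Linear trend",
                      100 * object$deviance_explained, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of pairwise beta components by level
#'
#' @param pairs Output of [beta_pairs()] with both levels.
#' @return A ggplot faceted by component.
#' @export
plot_beta_partition <- function(pairs) {
  long <- pivot_longer(pairs, c("beta_sor", "beta_turn", "beta_nes"),
                       names_to = "component", values_to = "value")
  long$component <- factor(long$component,
                           levels = c("beta_sor", "beta_turn", "beta_nes"),
                           labels = c("total", "turnover", "nestedness"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
                                     fill = .data$level)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = NULL, y = "pairwise dissimilarity") +
    ggplot2::theme_minimal()
}

#' Dominance profile of an assemblage
#'
#' Species ranked by IRI on a log scale, coloured by dominance class.
#'
#' @param iri Output of [iri_table()].
#' @param thresholds Dominance thresholds drawn as reference lines.
#' @return A ggplot.
#' @export
plot_iri <- function(iri, thresholds = c(500, 100)) {
  iri$species <- factor(iri$species, levels = rev(iri$species))
  ggplot2::ggplot(iri, ggplot2::aes(x = .data$iri, y = .data$species,
                                    colour = .data$class)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0.1, xend = .data$iri,
                                       yend = .data$species),
                          colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "IRI (log scale)", y = NULL, colour = "class") +
    ggplot2::theme_minimal()
}
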