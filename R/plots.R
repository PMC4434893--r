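#' Plot the total-degree distribution by node class
#'
#' Degree distributions of curated regulatory networks are strongly
#' right-skewed; this bar chart of total degree, faceted by node class,
#' makes the hub tail visible.
#'
#' @param net A `regulatory_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net) {
  d <- degrees(net)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_degree)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::labs(x = "Total degree (in + out)", y = "Nodes") +
    ggplot2::theme_minimal()
}

#' @rdname plot_degree_distribution
#' @param object A `regulatory_network`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.regulatory_network <- function(object, ...) {
  plot_degree_distribution(object)
}

#' Plot scored paths
#'
#' Coverage ratio against path length for scored paths, coloured by
#' `-log10` p-value, with the significance cutoff annotated.
#'
#' @param scored Scored path tibble from [score_paths()].
#' @param alpha Significance cutoff to annotate (default 0.001).
#' @return A ggplot object.
#' @export
plot_path_scores <- function(scored, alpha = 0.001) {
  ggplot2::ggplot(
    scored,
    ggplot2::aes(x = .data$length, y = .data$coverage_ratio,
                 colour = -log10(.data$p_value),
                 shape = .data$p_value < alpha)
  ) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10](p))) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 17, `FALSE` = 16),
      name = sprintf("p < %g", alpha)
    ) +
    ggplot2::labs(x = "Path length (nodes)", y = "Coverage ratio (known / length)") +
    ggplot2::theme_minimal()
}
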