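#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_path
#'   geom_text geom_hline geom_ribbon geom_errorbarh facet_wrap labs
#'   theme_minimal scale_color_manual coord_cartesian
NULL

#' Plot a network with a force-directed layout
#'
#' Nodes are placed by [fr_layout()]; positive edges are drawn in blue,
#' negative edges in red, with line width proportional to `|w|`.
#'
#' @param object a `psy_network`.
#' @param seed,iterations layout parameters.
#' @param label draw node labels.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psy_network <- function(object, seed = 1, iterations = 500,
                                 label = TRUE, ...) {
  xy <- fr_layout(object, iterations = iterations, seed = seed)
  edges <- tidy.psy_network(object) |>
    left_join(setNames(xy, c("from", "x0", "y0")), by = "from") |>
    left_join(setNames(xy, c("to", "x1", "y1")), by = "to") |>
    mutate(sign = ifelse(.data$weight > 0, "positive", "negative"))
  p <- ggplot() +
    geom_segment(
      data = edges,
      aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
          color = .data$sign, linewidth = abs(.data$weight)),
      alpha = 0.7, show.legend = FALSE
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    scale_color_manual(values = c(positive = "#2166ac", negative = "#b2182b")) +
    geom_point(data = xy, aes(.data$x, .data$y), size = 3,
               color = "grey30") +
    labs(title = sprintf("Layer: %s", object$layer)) +
    theme_minimal()
  if (label) {
    p <- p + geom_text(data = xy, aes(.data$x, .data$y, label = .data$node),
                       vjust = -1, size = 3)
  }
  p
}

#' Centrality profile plot (z-scored per index)
#'
#' @param object a `psy_centrality`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psy_centrality <- function(object, ...) {
  dat <- centrality_z(object)
  ggplot(dat, aes(x = .data$z, y = .data$node, group = .data$index)) +
    geom_path(color = "grey60") +
    geom_point() +
    facet_wrap(~index, nrow = 1) +
    labs(x = "z-score", y = NULL,
         title = sprintf("Centrality (%s layer)", attr(object, "layer"))) +
    theme_minimal()
}

#' Bootstrap edge-interval plot
#'
#' Edges ordered by point estimate with their 95% bootstrap intervals.
#'
#' @param object a `psy_edge_ci`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psy_edge_ci <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(edge = paste(.data$from, .data$to, sep = "--")) |>
    arrange(.data$point) |>
    mutate(edge = factor(.data$edge, levels = .data$edge))
  ggplot(dat, aes(y = .data$edge)) +
    geom_errorbarh(aes(xmin = .data$lower, xmax = .data$upper),
                   height = 0, color = "grey60") +
    geom_point(aes(x = .data$point), size = 0.8) +
    geom_hline(yintercept = 0, linetype = 0) +
    labs(x = "edge weight (partial correlation)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Case-dropping stability curves
#'
#' Mean centrality correlation (with 5th-percentile band) against the
#' proportion of cases dropped.
#'
#' @param object a `psy_stability`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psy_stability <- function(object, ...) {
  ggplot(object$curves,
         aes(.data$proportion, .data$mean_correlation, color = .data$index)) +
    geom_ribbon(aes(ymin = .data$q05, ymax = .data$mean_correlation,
                    fill = .data$index), alpha = 0.15, color = NA) +
    geom_path() +
    geom_point() +
    geom_hline(yintercept = attr(object, "cor_threshold"), linetype = 2) +
    coord_cartesian(ylim = c(-1, 1)) +
    labs(x = "proportion of cases dropped",
         y = "correlation with full sample") +
    theme_minimal()
}

#' @export
plot.psy_network <- function(x, ...) print(autoplot.psy_network(x, ...))

#' @export
plot.psy_centrality <- function(x, ...) print(autoplot.psy_centrality(x, ...))

#' @export
plot.psy_stability <- function(x, ...) print(autoplot.psy_stability(x, ...))
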