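#' Plot helpers for networks and layouts
#'
#' `autoplot()` methods turn layouts and fits into ggplot objects: node-link
#' diagrams draw edges with stroke width proportional to algorithm support
#' and nodes coloured by fold change (two-sample networks) or by entity kind
#' (multisample); treemaps draw the parent tiles with their equal-area
#' leaves and gene labels.
#'
#' @param object A `node_layout`, `treemap_layout` or `genmir_fit`.
#' @param network The `mirtar_network` a `node_layout` was computed from
#'   (needed to draw edges).
#' @param fc_cap Fold change at full colour saturation (see
#'   [fold_change_color()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @name plot_helpers
NULL

#' @rdname plot_helpers
#' @export
autoplot.node_layout <- function(object, network = NULL, fc_cap = 4, ...) {
  df <- as_tibble(object)
  p <- ggplot()
  if (!is.null(network)) {
    ed <- network$edges |>
      left_join(rename(df, mirna_id = node, x0 = x, y0 = y), by = "mirna_id") |>
      left_join(rename(select(df, node, x, y), mrna_id = node, x1 = x, y1 = y),
                by = "mrna_id")
    p <- p + geom_segment(
      data = ed,
      aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
          linewidth = .data$support),
      colour = "grey60", alpha = 0.7) +
      scale_linewidth(range = c(0.3, 2))
    if (!is.null(network$node_fc)) {
      df$fill <- fold_change_color(network$node_fc[df$node], cap = fc_cap)
    }
  }
  if (is.null(df$fill)) df$fill <- multisample_node_colors[df$type]
  p +
    geom_point(data = df,
               aes(.data$x, .data$y, shape = .data$type),
               fill = df$fill, size = 3, colour = "grey30", stroke = 0.4) +
    scale_shape_manual(values = c(miRNA = 23, mRNA = 21)) +
    scale_y_reverse() +
    coord_equal() +
    labs(x = NULL, y = NULL, shape = NULL) +
    theme_void() + theme(legend.position = "bottom")
}

#' @rdname plot_helpers
#' @export
autoplot.treemap_layout <- function(object, ...) {
  df <- as_tibble(object)
  par <- filter(df, depth == 0L)
  leaf <- filter(df, depth == 1L)
  ggplot() +
    geom_rect(data = leaf,
              aes(xmin = x, xmax = x + w, ymin = -(y + h), ymax = -y,
                  fill = parent),
              colour = "white", linewidth = 0.2, show.legend = FALSE) +
    geom_rect(data = par,
              aes(xmin = x, xmax = x + w, ymin = -(y + h), ymax = -y),
              fill = NA, colour = "grey20", linewidth = 0.8) +
    geom_text(data = leaf,
              aes(x = x + w / 2, y = -(y + h / 2), label = id),
              size = 2.4, colour = "grey10") +
    geom_text(data = par,
              aes(x = x + w / 2, y = -y, label = id),
              size = 2.8, vjust = 1.2, fontface = "bold") +
    coord_equal() +
    theme_void()
}

#' Render a plot to a file
#'
#' Thin wrapper over [ggplot2::ggsave()] so pipeline stages can emit static
#' PNG/PDF/SVG renders.
#'
#' @param plot A ggplot object.
#' @param path Output path; the device is inferred from the extension.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 8, height = 6) {
  ggsave(path, plot = plot, width = width, height = height)
  invisible(path)
}
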