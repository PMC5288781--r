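#' Plot a connectivity matrix as a probability heat map
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot: source islands on the y axis, destinations on x, tile
#'   fill on a log10 probability scale.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(
      source = factor(.data$source, levels = rev(rownames(object))),
      dest = factor(.data$dest, levels = colnames(object))
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$dest, .data$source, fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "grey90") +
    ggplot2::labs(x = "destination island", y = "source island",
                  fill = "P(connect)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an island partition
#'
#' Islands arranged on a circle, colored by community; edge segments scaled
#' by weight when the generating graph is supplied.
#'
#' @param object An `island_partition`.
#' @param graph Optional `conn_graph` for the edges.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.island_partition <- function(object, graph = NULL, ...) {
  memb <- object$membership
  n <- nrow(memb)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  nodes <- memb %>%
    mutate(x = cos(theta), y = sin(theta),
           community = factor(.data$community))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y))
  if (!is.null(graph)) {
    ed <- graph_edges(graph) %>%
      left_join(select(nodes, "island", "x", "y"), by = c(from = "island")) %>%
      rename(x0 = "x", y0 = "y") %>%
      left_join(select(nodes, "island", "x", "y"), by = c(to = "island"))
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linewidth = .data$weight),
      color = "grey70"
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(color = .data$community), size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$island), nudge_y = 0.12, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%d communities, Q = %.2f", object$n_communities, object$Q),
      color = "community"
    ) +
    ggplot2::theme_void()
}

#' Plot the GMYC threshold profile
#'
#' Profile log-likelihood across candidate threshold heights, with the
#' selected threshold marked; the standard diagnostic for a single-threshold
#' mixed Yule-coalescent fit.
#'
#' @param object A `gmyc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gmyc_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$threshold_height, .data$logLik)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$threshold_height,
                        linetype = "dashed", color = "red") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "candidate threshold height (root to the left)",
      y = "profile log-likelihood",
      title = sprintf("%d delimited entities", object$n_entities)
    ) +
    ggplot2::theme_minimal()
}
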