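# ggplot2 views of classification results.

#' Plot the inferred taxonomy of a classification
#'
#' Draws the direct-parent (transitive reduction) graph with a layered
#' Sugiyama layout: inferred subsumptions point upward, so a trait
#' polyhierarchy shows every reasoner-derived parent.
#'
#' @param object An `eq_classification`.
#' @param labels Optional named character vector id -> label used for
#'   node text (ids shown otherwise).
#' @param drop_isolated Hide classes with no parents and no children.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eq_classification <- function(object, labels = NULL,
                                       drop_isolated = TRUE, ...) {
  edges <- tidy_direct_parents(object)
  nodes <- unique(c(edges$child, edges$parent))
  if (!drop_isolated) nodes <- unique(c(nodes, object$classes))
  if (!length(nodes)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty taxonomy"))
  }
  g <- igraph::graph_from_data_frame(edges, vertices = nodes)
  lay <- igraph::layout_with_sugiyama(g)$layout
  pos <- tibble::tibble(
    id = nodes, x = lay[, 1], y = lay[, 2],
    label = if (is.null(labels)) nodes else {
      ifelse(is.na(labels[nodes]), nodes, labels[nodes])
    }
  )
  seg <- dplyr::left_join(edges, pos, by = c(child = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c(parent = "id")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey60"
    ) +
    ggplot2::geom_label(
      data = pos, ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 3
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "inferred taxonomy (direct parents)")
}

tidy_direct_parents <- function(result) {
  purrr::map_dfr(result$classes, function(C) {
    ps <- result$direct_parents[[C]]
    if (!length(ps)) return(NULL)
    tibble::tibble(child = C, parent = ps)
  })
}
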