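# ggplot2 presentation of the result objects.

#' @method autoplot posterior_tbl
#' @export
autoplot.posterior_tbl <- function(object, ...) {
  ev <- attr(object, "evidence")
  subtitle <- if (is.null(ev) || !length(ev)) {
    "No evidence (marginal posteriors)"
  } else {
    paste("Evidence:", paste(names(ev), unlist(ev), sep = " = ", collapse = ", "))
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$state, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~node, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Posterior probability", subtitle = subtitle) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot posterior shifts under evidence
#'
#' Diverging bars of the change in each node-state posterior relative to the
#' no-evidence baseline, the visual counterpart of the severity analysis.
#'
#' @param shift Tibble from [posterior_shift()].
#' @return A ggplot object.
#' @export
plot_posterior_shift <- function(shift) {
  ggplot2::ggplot(shift,
                  ggplot2::aes(x = .data$state, y = .data$shift_raw,
                               fill = .data$shift_raw > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~node, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey55")) +
    ggplot2::labs(x = NULL, y = "Posterior shift under evidence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot bn_dag
#' @export
autoplot.bn_dag <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$arcs, directed = TRUE,
    vertices = data.frame(name = object$nodes$node_id)
  )
  xy <- with_seed(42, igraph::layout_with_fr(g))  # layout only

  nodes_df <- tibble::tibble(
    node = object$nodes$node_id,
    tier = object$nodes$tier,
    x = xy[, 1],
    y = -object$nodes$tier + with_seed(43, stats::runif(nrow(object$nodes), -0.2, 0.2))
  )
  arcs_df <- dplyr::left_join(
    dplyr::left_join(object$arcs,
                     dplyr::rename(nodes_df, from = "node", x0 = "x", y0 = "y"),
                     by = "from"),
    dplyr::rename(nodes_df, to = "node", x1 = "x", y1 = "y"),
    by = "to"
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = arcs_df,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "grey50", alpha = 0.7
    ) +
    ggplot2::geom_label(
      data = nodes_df,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      size = 2.8
    ) +
    ggplot2::theme_void()
}
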