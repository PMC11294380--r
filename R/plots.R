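# ggplot2 views of the result types.

#' @method autoplot age_group_summary
#' @export
autoplot.age_group_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$stratum, y = .data$mean,
                               fill = .data$dimension)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "age group", y = "mean index score (centred)",
                  fill = "dimension") +
    ggplot2::theme_minimal()
}

#' @method autoplot mrt_cv
#' @export
autoplot.mrt_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$depth, y = .data$mse)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$fold), alpha = 0.3) +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(y = .data$mean_mse), linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$chosen_depth, linetype = 2) +
    ggplot2::labs(x = "tree depth", y = "held-out summed MSE",
                  title = paste0("cross-validated depth selection (chosen ",
                                 object$chosen_depth, ")")) +
    ggplot2::theme_minimal()
}

# node positions for plotting: recursive in-order layout
tree_layout <- function(nodes) {
  x <- numeric(nrow(nodes)); counter <- 0
  assign_x <- function(id) {
    i <- which(nodes$id == id)
    if (nodes$is_leaf[i]) {
      counter <<- counter + 1
      x[i] <<- counter
    } else {
      assign_x(nodes$left[i])
      assign_x(nodes$right[i])
      x[i] <<- (x[which(nodes$id == nodes$left[i])] +
                  x[which(nodes$id == nodes$right[i])]) / 2
    }
  }
  assign_x(1L)
  dplyr::mutate(nodes, x = x, y = -.data$depth)
}

#' @method autoplot mrt
#' @export
autoplot.mrt <- function(object, ...) {
  nodes <- tree_layout(object$nodes)
  edges <- nodes |>
    dplyr::filter(!.data$is_leaf) |>
    dplyr::reframe(child = c(.data$left, .data$right),
                   x = rep(.data$x, 2), y = rep(.data$y, 2)) |>
    dplyr::left_join(nodes[c("id", "x", "y")],
                     by = c(child = "id"), suffix = c("", "_child"))
  nodes$label <- ifelse(nodes$is_leaf, sprintf("n = %d", nodes$n),
                        sprintf("%s <= %g\nn = %d", nodes$feature,
                                nodes$threshold, nodes$n))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_child,
                                       yend = .data$y_child)) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label,
                                     fill = .data$squared_error),
                        colour = "white", size = 3) +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey65",
                                 name = "squared error") +
    ggplot2::theme_void()
}
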