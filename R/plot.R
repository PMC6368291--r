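#' Plot an airway tree projection
#'
#' Coronal (x-z) projection of the branch centerlines, colored by
#' generation. A quick visual check of phantom or reconstructed trees.
#'
#' @param object An [airway_tree()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.airway_tree <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   group = .data$branch_id,
                                   color = factor(.data$generation))) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, left)", y = "z (mm, superior)",
                  color = "generation",
                  title = "Airway tree, coronal projection") +
    ggplot2::theme_minimal()
}

#' Plot a route over its airway tree
#'
#' Coronal projection of the route from the trachea top to the centerline
#' point closest to the target, with the target marked; pass the tree to
#' draw the full airway for context.
#'
#' @param object An `airway_route` from [route_to_target()].
#' @param tree Optional [airway_tree()] drawn underneath.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.airway_route <- function(object, tree = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(tree)) {
    p <- p + ggplot2::geom_path(
      data = tidy(tree),
      ggplot2::aes(x = .data$x, y = .data$z, group = .data$branch_id),
      color = "grey70", linewidth = 0.6)
  }
  tgt <- object$target
  p +
    ggplot2::geom_path(data = object$positions,
                       ggplot2::aes(x = .data$x, y = .data$z),
                       color = "#D55E00", linewidth = 1.1) +
    ggplot2::geom_point(data = tgt, ggplot2::aes(x = .data$x, y = .data$z),
                        shape = 4, size = 3, stroke = 1.5,
                        color = tgt$color[1]) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, left)", y = "z (mm, superior)",
                  title = "Route to target, coronal projection") +
    ggplot2::theme_minimal()
}
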