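# ggplot2 views of a landscape fit: embedding coloured by pseudo-time with
# directed cluster paths, and the illustrative potential surface.

#' Plot a landscape fit
#'
#' Scatter of the first two embedding coordinates coloured by pseudo-time
#' (or cluster), with cluster centroids and the directed differentiation
#' paths drawn as arrows from high to low potential.
#'
#' @param object an `ldd` fit.
#' @param colour `"pseudotime"` or `"cluster"`.
#' @param arrows draw the directed path arrows.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot ldd
#' @export
autoplot.ldd <- function(object, colour = c("pseudotime", "cluster"),
                         arrows = TRUE, ...) {
  colour <- match.arg(colour)
  cells <- augment(object)
  cells$cluster_f <- factor(cells$cluster)
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = "PC1", y = "PC2")
  p <- if (colour == "pseudotime") {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$pseudotime), size = 1) +
      ggplot2::scale_colour_viridis_c(name = "pseudo-time")
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster_f), size = 1) +
      ggplot2::labs(colour = "cluster")
  }
  cent <- dplyr::summarise(dplyr::group_by(cells, .data$cluster),
                           PC1 = mean(.data$PC1), PC2 = mean(.data$PC2),
                           .groups = "drop")
  if (arrows && nrow(object$edges)) {
    seg <- dplyr::mutate(object$edges,
                         x = cent$PC1[.data$from], y = cent$PC2[.data$from],
                         xend = cent$PC1[.data$to], yend = cent$PC2[.data$to])
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches")),
      linewidth = 0.7, colour = "grey20")
  }
  p + ggplot2::geom_label(data = cent,
                          ggplot2::aes(label = .data$cluster), alpha = 0.7)
}

#' Plot the illustrative landscape surface
#'
#' Renders [landscape_surface()] as a filled raster with contours over the
#' first two embedding coordinates.
#'
#' @param fit an `ldd` fit.
#' @param ... passed to [landscape_surface()] (`sigma`, `a`, `b`, `cap`,
#'   `grid_n`, ...).
#' @return a ggplot object.
#' @export
plot_landscape_surface <- function(fit, ...) {
  surf <- landscape_surface(fit$embedding$coords, fit$labels,
                            fit$coarse$P_tilde, fit$V_hat, ...)
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$V)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$V), colour = "white",
                          alpha = 0.4, bins = 12) +
    ggplot2::scale_fill_viridis_c(name = "V(x, y)", na.value = "grey90") +
    ggplot2::labs(x = "PC1", y = "PC2")
}
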