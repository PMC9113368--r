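# ggplot2 preview of a layout: handy for interactive work; the publication
# path is render_figure(), whose SVG output is the tested surface.

#' Plot a layout with ggplot2
#'
#' Draws the same primitives as [render_figure()] — axis segments, ribbons,
#' marker glyphs and track bars — as a ggplot, for interactive inspection.
#'
#' @param object An `sr_layout`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sr_layout <- function(object, ...) {
  r <- object$ribbons
  poly <- NULL
  if (nrow(r)) {
    bx0 <- ifelse(r$crossed, r$bottom_x1, r$bottom_x0)
    bx1 <- ifelse(r$crossed, r$bottom_x0, r$bottom_x1)
    poly <- tibble(
      id = rep(seq_len(nrow(r)), each = 4),
      btype = rep(r$btype, each = 4),
      x = as.vector(rbind(r$top_x0, r$top_x1, bx1, bx0)),
      y = as.vector(rbind(r$top_y, r$top_y, r$bottom_y, r$bottom_y))
    )
  }
  cols <- unlist(object$config$colors)
  p <- ggplot2::ggplot()
  if (!is.null(poly)) {
    p <- p + ggplot2::geom_polygon(
      data = poly,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$btype),
      alpha = object$config$alpha
    ) +
      ggplot2::scale_fill_manual(values = cols, name = NULL)
  }
  p <- p + ggplot2::geom_segment(
    data = object$segments,
    ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y, yend = .data$y),
    linewidth = 1.2, colour = "grey20"
  )
  if (!is.null(object$trackbars) && nrow(object$trackbars)) {
    p <- p + ggplot2::geom_rect(
      data = object$trackbars,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = .data$y0,
                   ymax = .data$y1),
      fill = "cadetblue"
    )
  }
  if (!is.null(object$glyphs) && nrow(object$glyphs)) {
    p <- p + ggplot2::geom_point(
      data = object$glyphs,
      ggplot2::aes(x = .data$x, y = .data$y + 0.06),
      shape = 25, colour = object$glyphs$mc, fill = object$glyphs$mc,
      size = object$glyphs$ms / 2
    )
  }
  ylab_rows <- object$segments %>%
    distinct(.data$genome, .data$y)
  p +
    ggplot2::scale_y_continuous(breaks = ylab_rows$y,
                                labels = ylab_rows$genome) +
    ggplot2::labs(x = "position (Mb offset within column)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}
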