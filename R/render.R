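# render: turn layout primitives into a figure file, deterministically.
#
# SVG is the structured, diffable surface: exactly one <polygon> per ribbon,
# one <line> per axis segment, one <rect class="gap"> per not-aligned gap,
# one <rect class="trackbar"> per histogram bar, one <circle class="marker">
# per marker glyph; no timestamps or creator metadata, so identical inputs
# give byte-identical files. PDF and PNG go through grDevices.

#' Rendering configuration
#'
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution for PNG output (>= 50).
#' @param format `"pdf"`, `"png"`, `"svg"`, or `NULL` to infer from the
#'   output file extension.
#' @param font_size Base font size in points.
#' @param style Named list of style overrides.
#' @return An `sr_render_config` list.
#' @export
render_config <- function(width = 10, height = 6, dpi = 150, format = NULL,
                          font_size = 10, style = list()) {
  if (width <= 0 || height <= 0) abort("figure width and height must be > 0")
  if (!is.null(format) && !format %in% c("pdf", "png", "svg")) {
    abort("format must be one of pdf, png, svg")
  }
  if (dpi < 50) abort("dpi must be >= 50 for raster output")
  structure(list(width = width, height = height, dpi = dpi, format = format,
                 font_size = font_size, style = style),
            class = "sr_render_config")
}

#' Add genome labels and a block-type legend to a layout
#'
#' One text label per genome row (left of the row) and one legend entry per
#' block type actually present among the ribbons.
#'
#' @param layout An `sr_layout`.
#' @param enabled Set `FALSE` to suppress all legend elements.
#' @return The layout with `labels` and `legend` tibbles filled in.
#' @export
render_legend <- function(layout, enabled = TRUE) {
  stopifnot(inherits(layout, "sr_layout"))
  if (!enabled) {
    layout$labels <- NULL
    layout$legend <- NULL
    return(layout)
  }
  rows <- layout$segments %>%
    group_by(.data$genome) %>%
    summarise(y = .data$y[[1]], .groups = "drop") %>%
    arrange(dplyr::desc(.data$y))
  layout$labels <- tibble(text = rows$genome, y = rows$y)
  present <- intersect(names(layout$config$colors),
                       unique(layout$ribbons$btype))
  layout$legend <- tibble(
    btype = present,
    color = unname(unlist(layout$config$colors)[present])
  )
  layout
}

#' Render a layout to a figure file
#'
#' @param layout An `sr_layout` (optionally already passed through
#'   [place_tracks_and_markers()] and [render_legend()]).
#' @param config An [render_config()].
#' @param out_path Output file; the extension selects the format when
#'   `config$format` is `NULL`.
#' @return Invisibly, `out_path`.
#' @export
render_figure <- function(layout, config = render_config(), out_path) {
  stopifnot(inherits(layout, "sr_layout"))
  if (nrow(layout$segments) == 0 && nrow(layout$ribbons) == 0) {
    abort("nothing to draw: the layout holds zero primitives")
  }
  fmt <- config$format
  if (is.null(fmt)) {
    fmt <- tolower(tools::file_ext(out_path))
    if (!fmt %in% c("pdf", "png", "svg")) {
      abort(paste0("cannot infer output format from '", out_path,
                   "'; supported: pdf, png, svg"))
    }
  }
  switch(fmt,
         svg = render_svg(layout, config, out_path),
         pdf = render_grid(layout, config, out_path, "pdf"),
         png = render_grid(layout, config, out_path, "png"))
  invisible(out_path)
}

# Fixed-precision coordinate formatting keeps SVG output byte-stable.
fmt_px <- function(x) sprintf("%.2f", x)

layout_bounds <- function(layout) {
  xs <- c(layout$segments$x0, layout$segments$x1,
          layout$ribbons$top_x0, layout$ribbons$top_x1,
          layout$ribbons$bottom_x0, layout$ribbons$bottom_x1)
  ys <- c(layout$segments$y, layout$ribbons$top_y, layout$ribbons$bottom_y)
  if (!is.null(layout$trackbars) && nrow(layout$trackbars)) {
    xs <- c(xs, layout$trackbars$x0, layout$trackbars$x1)
    ys <- c(ys, layout$trackbars$y0, layout$trackbars$y1)
  }
  list(xmin = min(xs), xmax = max(xs),
       ymin = min(ys) - 0.3, ymax = max(ys) + 0.3)
}

render_svg <- function(layout, config, out_path) {
  W <- config$width * 90
  H <- config$height * 90
  has_labels <- !is.null(layout$labels) && nrow(layout$labels) > 0
  ml <- if (has_labels) 90 else 20
  mr <- 20; mt <- 20
  mb <- if (!is.null(layout$legend) && nrow(layout$legend)) 46 else 20
  b <- layout_bounds(layout)
  sx <- (W - ml - mr) / max(b$xmax - b$xmin, 1e-9)
  sy <- (H - mt - mb) / max(b$ymax - b$ymin, 1e-9)
  px <- function(x) ml + (x - b$xmin) * sx
  py <- function(y) mt + (b$ymax - y) * sy   # y grows upward in layout units

  vertical <- isTRUE(config$style$vertical)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    if (vertical) {
      # genomes as columns: the whole figure is one 90-degree transform
      sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                     'width="%s" height="%s" viewBox="0 0 %s %s">'),
              fmt_px(H), fmt_px(W), fmt_px(H), fmt_px(W))
    } else {
      sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                     'width="%s" height="%s" viewBox="0 0 %s %s">'),
              fmt_px(W), fmt_px(H), fmt_px(W), fmt_px(H))
    },
    if (vertical) {
      sprintf('<g transform="rotate(90) translate(0 %s)">', fmt_px(-H))
    }
  )

  r <- layout$ribbons
  if (nrow(r)) {
    # crossed ribbons swap the bottom corner order to draw the X shape
    bx0 <- ifelse(r$crossed, r$bottom_x1, r$bottom_x0)
    bx1 <- ifelse(r$crossed, r$bottom_x0, r$bottom_x1)
    out <- c(out, sprintf(
      paste0('<polygon class="ribbon ribbon-%s" points="%s,%s %s,%s %s,%s ',
             '%s,%s" fill="%s" fill-opacity="%s" stroke="none"/>'),
      r$btype,
      fmt_px(px(r$top_x0)), fmt_px(py(r$top_y)),
      fmt_px(px(r$top_x1)), fmt_px(py(r$top_y)),
      fmt_px(px(bx1)), fmt_px(py(r$bottom_y)),
      fmt_px(px(bx0)), fmt_px(py(r$bottom_y)),
      r$color, layout$config$alpha))
  }

  s <- layout$segments
  if (nrow(s)) {
    out <- c(out, sprintf(
      paste0('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" ',
             'stroke="#333333" stroke-width="2"/>'),
      fmt_px(px(s$x0)), fmt_px(py(s$y)), fmt_px(px(s$x1)), fmt_px(py(s$y))))
  }

  g <- layout$gaps
  if (!is.null(g) && nrow(g)) {
    out <- c(out, sprintf(
      paste0('<rect class="gap" x="%s" y="%s" width="%s" height="4" ',
             'fill="#ffffff"/>'),
      fmt_px(px(g$x0)), fmt_px(py(g$y) - 2),
      fmt_px(pmax(px(g$x1) - px(g$x0), 0.5))))
  }

  tb <- layout$trackbars
  if (!is.null(tb) && nrow(tb)) {
    out <- c(out, sprintf(
      paste0('<rect class="trackbar" x="%s" y="%s" width="%s" height="%s" ',
             'fill="%s"/>'),
      fmt_px(px(tb$x0)), fmt_px(py(tb$y1)),
      fmt_px(pmax(px(tb$x1) - px(tb$x0), 0.25)),
      fmt_px(pmax(py(tb$y0) - py(tb$y1), 0)), tb$color))
  }

  gl <- layout$glyphs
  if (!is.null(gl) && nrow(gl)) {
    out <- c(out, sprintf(
      '<circle class="marker" cx="%s" cy="%s" r="%s" fill="%s"/>',
      fmt_px(px(gl$x)), fmt_px(py(gl$y) - 5), fmt_px(gl$ms), gl$mc))
    lab <- gl[nzchar(gl$label), , drop = FALSE]
    if (nrow(lab)) {
      out <- c(out, sprintf(
        paste0('<text class="marker-label" x="%s" y="%s" font-size="%s" ',
               'text-anchor="middle">%s</text>'),
        fmt_px(px(lab$x)), fmt_px(py(lab$y) - 10), config$font_size,
        xml_escape(lab$label)))
    }
  }

  if (!is.null(layout$labels) && nrow(layout$labels)) {
    out <- c(out, sprintf(
      paste0('<text class="row-label" x="%s" y="%s" font-size="%s" ',
             'text-anchor="end">%s</text>'),
      fmt_px(ml - 8), fmt_px(py(layout$labels$y) + 3), config$font_size,
      xml_escape(layout$labels$text)))
  }

  lg <- layout$legend
  if (!is.null(lg) && nrow(lg)) {
    lx <- ml + (seq_len(nrow(lg)) - 1) * 80
    ly <- H - 18
    out <- c(out,
             sprintf(paste0('<rect class="legend-swatch" x="%s" y="%s" ',
                            'width="14" height="10" fill="%s"/>'),
                     fmt_px(lx), fmt_px(ly), lg$color),
             sprintf(paste0('<text class="legend-label" x="%s" y="%s" ',
                            'font-size="%s">%s</text>'),
                     fmt_px(lx + 18), fmt_px(ly + 9), config$font_size,
                     xml_escape(lg$btype)))
  }

  out <- c(out, if (vertical) "</g>", "</svg>")
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(out_path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_grid <- function(layout, config, out_path, device) {
  if (device == "pdf") {
    grDevices::pdf(out_path, width = config$width, height = config$height,
                   useDingbats = FALSE)
  } else {
    grDevices::png(out_path, width = config$width * config$dpi,
                   height = config$height * config$dpi, res = config$dpi)
  }
  on.exit(grDevices::dev.off())
  b <- layout_bounds(layout)
  grid::grid.newpage()
  vp <- grid::viewport(x = 0.5, y = 0.5, width = 0.92, height = 0.9,
                       xscale = c(b$xmin, b$xmax), yscale = c(b$ymin, b$ymax),
                       angle = if (isTRUE(config$style$vertical)) 90 else 0)
  grid::pushViewport(vp)
  r <- layout$ribbons
  if (nrow(r)) {
    bx0 <- ifelse(r$crossed, r$bottom_x1, r$bottom_x0)
    bx1 <- ifelse(r$crossed, r$bottom_x0, r$bottom_x1)
    for (i in seq_len(nrow(r))) {
      grid::grid.polygon(
        x = c(r$top_x0[i], r$top_x1[i], bx1[i], bx0[i]),
        y = c(r$top_y[i], r$top_y[i], r$bottom_y[i], r$bottom_y[i]),
        default.units = "native",
        gp = grid::gpar(fill = grDevices::adjustcolor(r$color[i],
                                                      layout$config$alpha),
                        col = NA))
    }
  }
  s <- layout$segments
  if (nrow(s)) {
    grid::grid.segments(x0 = s$x0, y0 = s$y, x1 = s$x1, y1 = s$y,
                        default.units = "native",
                        gp = grid::gpar(lwd = 2, col = "#333333"))
  }
  tb <- layout$trackbars
  if (!is.null(tb) && nrow(tb)) {
    grid::grid.rect(x = (tb$x0 + tb$x1) / 2, y = (tb$y0 + tb$y1) / 2,
                    width = pmax(tb$x1 - tb$x0, 1e-6),
                    height = pmax(tb$y1 - tb$y0, 1e-6),
                    default.units = "native",
                    gp = grid::gpar(fill = tb$color, col = NA))
  }
  gl <- layout$glyphs
  if (!is.null(gl) && nrow(gl)) {
    grid::grid.points(x = gl$x, y = gl$y + 0.06, default.units = "native",
                      pch = 25, size = grid::unit(gl$ms, "points"),
                      gp = grid::gpar(col = gl$mc, fill = gl$mc))
  }
  if (!is.null(layout$labels) && nrow(layout$labels)) {
    grid::grid.text(layout$labels$text,
                    x = grid::unit(0, "npc") - grid::unit(2, "mm"),
                    y = grid::unit(layout$labels$y, "native"),
                    just = "right",
                    gp = grid::gpar(fontsize = config$font_size))
  }
  grid::popViewport()
  invisible(out_path)
}
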