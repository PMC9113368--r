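# layout: convert a validated (possibly zoom-clipped) chain plus homology
# groups into device-independent drawing primitives.
#
# Figure units: 1 unit per megabase horizontally, 1 unit per genome row
# vertically; genome 1 occupies the top row. All primitives carry enough
# information to invert the base-pair -> x mapping exactly.

MB <- 1e6

DEFAULT_RIBBON_COLORS <- c(
  SYN = "#bfbfbf", INV = "#ffa500", TRANS = "#2e8b57", INVTR = "#9acd32",
  DUP = "#4169e1", INVDP = "#87cefa"
)

layout_config <- function(overrides = list()) {
  cfg <- list(
    colors = DEFAULT_RIBBON_COLORS,
    alpha = 0.75,
    axis_margin = 0.08,   # vertical gap between an axis line and its ribbons
    row_spacing = 1,      # vertical distance between genome rows
    gap_frac = 0.02,      # itx inter-chromosome gap, fraction of longest genome
    track_height = 0.6    # height of a full track bar, in row units
  )
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg[["colors"]] <- utils::modifyList(as.list(DEFAULT_RIBBON_COLORS),
                                       as.list(cfg[["colors"]]))
  cfg
}

empty_segments <- function() {
  tibble(genome = character(), chrom = character(), x0 = double(),
         x1 = double(), y = double(), bp0 = double(), bp1 = double())
}

empty_ribbons <- function() {
  tibble(btype = character(), source_id = character(),
         top_genome = character(), bottom_genome = character(),
         top_chrom = character(), bottom_chrom = character(),
         top_x0 = double(), top_x1 = double(), top_y = double(),
         bottom_x0 = double(), bottom_x1 = double(), bottom_y = double(),
         crossed = logical(), color = character())
}

empty_gaps <- function() {
  tibble(genome = character(), chrom = character(), x0 = double(),
         x1 = double(), y = double())
}

new_layout <- function(segments, ribbons, gaps, mode, n_rows, config) {
  structure(list(segments = segments, ribbons = ribbons, gaps = gaps,
                 glyphs = NULL, trackbars = NULL, labels = NULL,
                 legend = NULL, mode = mode, n_rows = n_rows,
                 config = config),
            class = "sr_layout")
}

# Drawn interval per (genome, chrom): the zoom window when given, the whole
# chromosome otherwise.
drawn_intervals <- function(chain, selection = NULL) {
  if (is.null(selection)) {
    purrr::imap_dfr(chain$genomes, function(g, name) {
      tibble(genome = name, chrom = g$chromosomes$name,
             bp0 = 1, bp1 = g$chromosomes$length)
    })
  } else {
    tibble(genome = selection$genome, chrom = selection$chrom,
           bp0 = selection$start, bp1 = selection$end)
  }
}

seg_x <- function(segments, genome, chrom, bp) {
  i <- match(paste(genome, chrom), paste(segments$genome, segments$chrom))
  segments$x0[i] + (bp - segments$bp0[i]) / MB
}

# Build ribbons for one comparison given placed segments; blocks whose
# chromosome pair is not drawn yield NULL entries filtered by the caller.
make_ribbons <- function(blocks, ref_genome, qry_genome, segments, cfg) {
  drawable <- blocks$btype %in% RIBBON_TYPES
  b <- blocks[drawable, , drop = FALSE]
  key <- paste(segments$genome, segments$chrom)
  top_ok <- paste(ref_genome, b$ref_chrom) %in% key
  bot_ok <- paste(qry_genome, b$qry_chrom) %in% key
  b <- b[top_ok & bot_ok, , drop = FALSE]
  if (!nrow(b)) return(list(ribbons = empty_ribbons(), skipped = sum(drawable)))
  top_y_axis <- segments$y[match(paste(ref_genome, b$ref_chrom), key)]
  bot_y_axis <- segments$y[match(paste(qry_genome, b$qry_chrom), key)]
  ribbons <- tibble(
    btype = b$btype,
    source_id = b$source_id,
    top_genome = ref_genome, bottom_genome = qry_genome,
    top_chrom = b$ref_chrom, bottom_chrom = b$qry_chrom,
    top_x0 = seg_x(segments, ref_genome, b$ref_chrom, b$ref_start),
    top_x1 = seg_x(segments, ref_genome, b$ref_chrom, b$ref_end),
    top_y = top_y_axis - cfg$axis_margin,
    bottom_x0 = seg_x(segments, qry_genome, b$qry_chrom, b$qry_start),
    bottom_x1 = seg_x(segments, qry_genome, b$qry_chrom, b$qry_end),
    bottom_y = bot_y_axis + cfg$axis_margin,
    crossed = b$btype %in% INVERTED_TYPES,
    color = unname(unlist(cfg$colors)[b$btype])
  )
  list(ribbons = ribbons, skipped = sum(drawable) - nrow(b))
}

make_gaps <- function(blocks, ref_genome, qry_genome, segments) {
  b <- blocks[blocks$btype == "NOTAL", , drop = FALSE]
  if (!nrow(b)) return(empty_gaps())
  key <- paste(segments$genome, segments$chrom)
  side <- function(genome, chrom, start, end) {
    ok <- !is.na(chrom) & paste(genome, chrom) %in% key
    tibble(genome = genome, chrom = chrom[ok],
           x0 = seg_x(segments, genome, chrom[ok], start[ok]),
           x1 = seg_x(segments, genome, chrom[ok], end[ok]),
           y = segments$y[match(paste(genome, chrom[ok]), key)])
  }
  bind_rows(side(ref_genome, b$ref_chrom, b$ref_start, b$ref_end),
            side(qry_genome, b$qry_chrom, b$qry_start, b$qry_end))
}

#' Stacked-mode figure layout
#'
#' Each genome occupies one horizontal row (genome 1 on top). Homologous
#' chromosomes form vertical columns sharing a left-aligned x origin, so
#' syntenic and intra-chromosomal rearrangement ribbons run straight down a
#' column. Blocks connecting chromosomes of different homology groups
#' (inter-chromosomal translocations/duplications) are not drawable in this
#' mode; they are skipped and their count reported.
#'
#' @param chain An `sr_chain` (possibly zoom-clipped by
#'   [clip_to_selection()]).
#' @param groups Homology groups from [chain_homology()].
#' @param selection Optional `sr_zoom`; restricts drawing to the selected
#'   windows.
#' @param config Named list of layout style overrides (colors, spacing, ...).
#' @return An `sr_layout` with `segments`, `ribbons` and `gaps` tibbles; the
#'   number of skipped inter-chromosomal blocks is in the
#'   `skipped_inter_chromosomal` attribute.
#' @export
layout_stacked <- function(chain, groups, selection = NULL, config = list()) {
  stopifnot(inherits(chain, "sr_chain"))
  cfg <- layout_config(config)
  gnames <- names(chain$genomes)
  n <- length(gnames)
  drawn <- drawn_intervals(chain, selection) %>%
    left_join(groups, by = c("genome", "chrom"))
  if (any(is.na(drawn$order_index))) {
    drawn <- drawn %>% filter(!is.na(.data$order_index))
  }
  # column origin per homology group: cumulative max drawn width
  widths <- drawn %>%
    group_by(.data$order_index) %>%
    summarise(w = max(.data$bp1 - .data$bp0 + 1) / MB, .groups = "drop") %>%
    arrange(.data$order_index)
  col_gap <- cfg$gap_frac * sum(widths$w)
  widths$x_origin <- cumsum(c(0, head(widths$w + col_gap, -1)))
  segments <- drawn %>%
    left_join(widths, by = "order_index") %>%
    mutate(
      x0 = .data$x_origin,
      x1 = .data$x_origin + (.data$bp1 - .data$bp0 + 1) / MB,
      y = (n - match(.data$genome, gnames)) * cfg$row_spacing
    ) %>%
    select("genome", "chrom", "x0", "x1", "y", "bp0", "bp1")

  grp_key <- paste(groups$genome, groups$chrom)
  grp_of <- function(genome, chrom) {
    groups$order_index[match(paste(genome, chrom), grp_key)]
  }
  ribbons <- empty_ribbons(); gaps <- empty_gaps(); skipped <- 0L
  for (cmp in chain$comparisons) {
    b <- cmp$blocks
    gr <- grp_of(cmp$ref_genome, b$ref_chrom)
    gq <- grp_of(cmp$qry_genome, b$qry_chrom)
    same_group <- !is.na(gr) & !is.na(gq) & gr == gq
    same_group[is.na(same_group)] <- FALSE
    intra <- b[same_group | b$btype == "NOTAL", , drop = FALSE]
    skipped <- skipped +
      sum(!same_group & b$btype %in% RIBBON_TYPES, na.rm = TRUE)
    made <- make_ribbons(intra, cmp$ref_genome, cmp$qry_genome, segments, cfg)
    ribbons <- bind_rows(ribbons, made$ribbons)
    gaps <- bind_rows(gaps, make_gaps(intra, cmp$ref_genome, cmp$qry_genome,
                                      segments))
  }
  if (skipped > 0) {
    inform(paste0("stacked mode: skipped ", skipped,
                  " inter-chromosomal block(s); use itx mode to draw them"))
  }
  out <- new_layout(segments, ribbons, gaps, "stacked", n, cfg)
  attr(out, "skipped_inter_chromosomal") <- skipped
  out
}

#' itx-mode figure layout
#'
#' Each genome's chromosomes are concatenated on a single row, ordered by
#' homology group and separated by a fixed gap (default 2% of the longest
#' genome's drawn length), in the style of whole-genome macrosynteny plots.
#' Every block type produces a ribbon, including inter-chromosomal
#' translocations and duplications whose anchors lie in different segments.
#'
#' @inheritParams layout_stacked
#' @param selection Must be `NULL`: zooming cannot be combined with itx mode.
#' @return An `sr_layout`.
#' @export
layout_itx <- function(chain, groups, selection = NULL, config = list()) {
  stopifnot(inherits(chain, "sr_chain"))
  if (!is.null(selection)) {
    abort("itx mode cannot be combined with a zoom region")
  }
  cfg <- layout_config(config)
  gnames <- names(chain$genomes)
  n <- length(gnames)
  drawn <- drawn_intervals(chain) %>%
    left_join(groups, by = c("genome", "chrom")) %>%
    arrange(match(.data$genome, gnames), .data$order_index)
  longest <- drawn %>%
    group_by(.data$genome) %>%
    summarise(total = sum(.data$bp1 - .data$bp0 + 1) / MB, .groups = "drop")
  gap <- cfg$gap_frac * max(longest$total)
  segments <- drawn %>%
    group_by(.data$genome) %>%
    mutate(
      w = (.data$bp1 - .data$bp0 + 1) / MB,
      x0 = cumsum(c(0, head(.data$w + gap, -1))),
      x1 = .data$x0 + .data$w,
      y = (n - match(.data$genome[[1]], gnames)) * cfg$row_spacing
    ) %>%
    ungroup() %>%
    select("genome", "chrom", "x0", "x1", "y", "bp0", "bp1")

  ribbons <- empty_ribbons(); gaps <- empty_gaps()
  for (cmp in chain$comparisons) {
    made <- make_ribbons(cmp$blocks, cmp$ref_genome, cmp$qry_genome,
                         segments, cfg)
    ribbons <- bind_rows(ribbons, made$ribbons)
    gaps <- bind_rows(gaps, make_gaps(cmp$blocks, cmp$ref_genome,
                                      cmp$qry_genome, segments))
  }
  new_layout(segments, ribbons, gaps, "itx", n, cfg)
}

#' Add marker glyphs and track histograms to a layout
#'
#' Markers become glyphs at their mapped x position on their genome's row,
#' with optional text labels. Each track occupies a dedicated row above
#' genome 1, in the order given; bar heights are normalized to the track's
#' maximum inside the drawn window (an all-zero track stays flat at zero).
#'
#' @param layout An `sr_layout`.
#' @param markers Marker tibble from [parse_markers()], or `NULL`.
#' @param tracks List of binned track tibbles from [load_track_values()]
#'   (all bound to genome 1 coordinates), or `NULL`.
#' @return The layout with `glyphs` and `trackbars` tibbles filled in.
#' @export
place_tracks_and_markers <- function(layout, markers = NULL, tracks = NULL) {
  stopifnot(inherits(layout, "sr_layout"))
  segments <- layout$segments
  cfg <- layout$config
  key <- paste(segments$genome, segments$chrom)

  glyphs <- tibble(genome = character(), chrom = character(), x = double(),
                   y = double(), mt = character(), mc = character(),
                   ms = double(), label = character(), tp = character())
  if (!is.null(markers) && nrow(markers)) {
    for (i in seq_len(nrow(markers))) {
      m <- markers[i, ]
      j <- match(paste(m$genome, m$chrom), key)
      if (is.na(j) || m$start < segments$bp0[[j]] ||
          m$start > segments$bp1[[j]]) {
        warn(paste0("marker at ", m$genome, "/", m$chrom, ":", m$start,
                    " lies outside every drawn segment; skipped"))
        next
      }
      glyphs <- bind_rows(glyphs, tibble(
        genome = m$genome, chrom = m$chrom,
        x = seg_x(segments, m$genome, m$chrom, m$start),
        y = segments$y[[j]], mt = m$mt, mc = m$mc, ms = m$ms,
        label = m$label, tp = m$tp
      ))
    }
  }

  trackbars <- tibble(track = character(), x0 = double(), x1 = double(),
                      y0 = double(), y1 = double(), color = character())
  if (!is.null(tracks) && length(tracks)) {
    g1 <- segments$genome[segments$y == max(segments$y)][[1]]
    base_y <- max(segments$y)
    for (r in seq_along(tracks)) {
      tr <- tracks[[r]]
      row_y <- base_y + r * cfg$row_spacing
      seg1 <- segments[segments$genome == g1, , drop = FALSE]
      tr <- tr %>%
        left_join(seg1 %>% select("chrom", "x0", "bp0", "bp1"),
                  by = "chrom") %>%
        filter(!is.na(.data$x0),
               .data$bin_start <= .data$bp1, .data$bin_end >= .data$bp0)
      if (!nrow(tr)) next
      vmax <- max(tr$value)
      h <- if (vmax > 0) cfg$track_height * tr$value / vmax else rep(0, nrow(tr))
      trackbars <- bind_rows(trackbars, tibble(
        track = tr$track,
        x0 = tr$x0 + (pmax(tr$bin_start, tr$bp0) - tr$bp0) / MB,
        x1 = tr$x0 + (pmin(tr$bin_end, tr$bp1) - tr$bp0 + 1) / MB,
        y0 = row_y,
        y1 = row_y + h,
        color = "#5f9ea0"
      ))
    }
  }
  layout$glyphs <- glyphs
  layout$trackbars <- trackbars
  layout
}

#' Tidy a layout into one row per ribbon
#'
#' @param x An `sr_layout`.
#' @param ... Unused.
#' @export
tidy.sr_layout <- function(x, ...) x$ribbons

#' One-row summary of a layout
#'
#' @param x An `sr_layout`.
#' @param ... Unused.
#' @export
glance.sr_layout <- function(x, ...) {
  tibble(mode = x$mode,
         n_segments = nrow(x$segments),
         n_ribbons = nrow(x$ribbons),
         n_gaps = nrow(x$gaps),
         n_glyphs = if (is.null(x$glyphs)) 0L else nrow(x$glyphs),
         n_trackbars = if (is.null(x$trackbars)) 0L else nrow(x$trackbars))
}

#' @export
print.sr_layout <- function(x, ...) {
  g <- glance(x)
  cat("<sr_layout> mode=", g$mode, " segments=", g$n_segments,
      " ribbons=", g$n_ribbons, " gaps=", g$n_gaps, "\n", sep = "")
  invisible(x)
}
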