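# zoom: given one region in one genome, find the homologous interval in every
# other genome by iterative propagation through the pairwise syntenic
# backbone, then restrict all drawable content to those intervals.
#
# Only SYN blocks drive propagation; rearrangement blocks are passengers.

#' Describe a zoom region request
#'
#' @param genome Genome name.
#' @param chrom Chromosome name within that genome.
#' @param start,end 1-based inclusive interval in base pairs.
#' @return An `sr_region` list.
#' @export
region_request <- function(genome, chrom, start, end) {
  start <- as.double(start); end <- as.double(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end) {
    abort(paste0("invalid region ", chrom, ":", start, "-", end,
                 " (need 1 <= start <= end)"))
  }
  structure(list(genome = genome, chrom = chrom, start = start, end = end),
            class = "sr_region")
}

#' Parse a GENOME:CHROM:START-END region string
#'
#' Coordinates are 1-based inclusive; thousands separators (`,`) are allowed.
#'
#' @param text Region string, e.g. `"refgen:Chr8:1-13000000"`.
#' @return An `sr_region` as from [region_request()].
#' @export
parse_region <- function(text) {
  m <- regexec("^(.*):([^:]+):([0-9][0-9,]*)-([0-9][0-9,]*)$", text)[[1]]
  if (m[[1]] < 0) {
    abort(paste0("malformed region '", text,
                 "': expected GENOME:CHROM:START-END (1-based inclusive)"))
  }
  g <- regmatches(text, list(m))[[1]]
  region_request(g[[2]], g[[3]],
                 as.double(gsub(",", "", g[[4]], fixed = TRUE)),
                 as.double(gsub(",", "", g[[5]], fixed = TRUE)))
}

#' Map a region across one pairwise comparison
#'
#' Among SYN blocks whose source-side interval overlaps the region, the
#' homologous chromosome is the one carrying the most overlapping syntenic
#' sequence (ties broken lexicographically). Each region endpoint is then
#' mapped by linear interpolation within its containing block, with floor
#' rounding; an endpoint falling in an inter-block gap maps to the nearest
#' edge of the adjacent block's counterpart. The result is the (min, max) of
#' the two mapped endpoints, which also handles locally inverted block
#' order, clipped to the target chromosome.
#'
#' @param region List or `sr_region` with `chrom`, `start`, `end` on the
#'   source side.
#' @param comparison An [pairwise_comparison()] object.
#' @param direction `"ref2qry"` (region is in the reference-side genome) or
#'   `"qry2ref"`.
#' @param target_length Optional length of the target chromosome for
#'   clipping; `Inf` disables the upper clip.
#' @return A list `(chrom, start, end)` on the target side.
#' @export
map_region_step <- function(region, comparison,
                            direction = c("ref2qry", "qry2ref"),
                            target_length = Inf) {
  direction <- match.arg(direction)
  src <- if (direction == "ref2qry") "ref" else "qry"
  tgt <- if (direction == "ref2qry") "qry" else "ref"
  blocks <- comparison$blocks
  syn <- blocks[blocks$btype == "SYN" &
                  !is.na(blocks[[paste0(src, "_chrom")]]) &
                  blocks[[paste0(src, "_chrom")]] == region$chrom, , drop = FALSE]
  ss <- syn[[paste0(src, "_start")]]; se <- syn[[paste0(src, "_end")]]
  ov <- which(ss <= region$end & se >= region$start)
  if (!length(ov)) {
    abort(paste0("zoom propagation dead-ends: no SYN block of comparison ",
                 comparison$ref_genome %||% "?", " vs ",
                 comparison$qry_genome %||% "?", " overlaps ",
                 region$chrom, ":", region$start, "-", region$end))
  }
  syn <- syn[ov, , drop = FALSE]
  ss <- ss[ov]; se <- se[ov]
  tchrom_all <- syn[[paste0(tgt, "_chrom")]]
  ovl_bp <- pmin(se, region$end) - pmax(ss, region$start) + 1
  by_chrom <- tapply(ovl_bp, tchrom_all, sum)
  target_chrom <- names(by_chrom)[order(-by_chrom, names(by_chrom))][[1]]
  keep <- tchrom_all == target_chrom
  syn <- syn[keep, , drop = FALSE]; ss <- ss[keep]; se <- se[keep]
  ts <- syn[[paste0(tgt, "_start")]]; te <- syn[[paste0(tgt, "_end")]]
  inv <- syn$inverted

  map_point <- function(p) {
    inside <- which(ss <= p & se >= p)
    if (length(inside)) {
      i <- inside[[order(ss[inside])[[1]]]]
      frac_num <- (p - ss[[i]]) * (te[[i]] - ts[[i]])
      off <- if (se[[i]] > ss[[i]]) floor(frac_num / (se[[i]] - ss[[i]])) else 0
      if (inv[[i]]) te[[i]] - off else ts[[i]] + off
    } else {
      # gap: nearest source edge of the adjacent overlapping block
      d_left <- ifelse(se < p, p - se, Inf)   # block entirely left of p
      d_right <- ifelse(ss > p, ss - p, Inf)  # block entirely right of p
      i <- which.min(pmin(d_left, d_right))
      if (d_right[[i]] <= d_left[[i]]) {
        if (inv[[i]]) te[[i]] else ts[[i]]    # counterpart of source start edge
      } else {
        if (inv[[i]]) ts[[i]] else te[[i]]    # counterpart of source end edge
      }
    }
  }
  a <- map_point(region$start)
  b <- map_point(region$end)
  list(chrom = target_chrom,
       start = max(1, min(a, b)),
       end = min(target_length, max(a, b)))
}

#' Propagate a zoom region to every genome of the chain
#'
#' Starting from the requested genome, [map_region_step()] is applied
#' outward in both directions along the chain until the ends are reached, so
#' each genome receives exactly one homologous interval.
#'
#' @param request An `sr_region` from [region_request()] or [parse_region()].
#' @param chain An `sr_chain`.
#' @return An `sr_zoom` tibble with one row per genome (`genome`, `chrom`,
#'   `start`, `end`, in chain order); the originating request is kept in the
#'   `origin` attribute.
#' @export
propagate_region <- function(request, chain) {
  stopifnot(inherits(chain, "sr_chain"))
  gnames <- names(chain$genomes)
  i0 <- match(request$genome, gnames)
  if (is.na(i0)) {
    abort(paste0("region names unknown genome '", request$genome, "'"))
  }
  chroms <- chain$genomes[[i0]]$chromosomes
  len <- chroms$length[match(request$chrom, chroms$name)]
  if (is.na(len)) {
    abort(paste0("region names unknown chromosome '", request$chrom,
                 "' of genome ", request$genome))
  }
  if (request$end > len) {
    abort(paste0("region ", request$chrom, ":", request$start, "-",
                 request$end, " exceeds the ", len, " bp chromosome"))
  }
  n <- length(gnames)
  iv <- vector("list", n)
  iv[[i0]] <- list(chrom = request$chrom, start = request$start,
                   end = request$end)
  chrom_len <- function(g, chrom) {
    tab <- chain$genomes[[g]]$chromosomes
    tab$length[match(chrom, tab$name)]
  }
  if (i0 < n) {
    for (k in i0:(n - 1L)) {
      step <- map_region_step(iv[[k]], chain$comparisons[[k]], "ref2qry")
      step$end <- min(step$end, chrom_len(k + 1L, step$chrom))
      iv[[k + 1L]] <- step
    }
  }
  if (i0 > 1L) {
    for (k in (i0 - 1L):1L) {
      step <- map_region_step(iv[[k + 1L]], chain$comparisons[[k]], "qry2ref")
      step$end <- min(step$end, chrom_len(k, step$chrom))
      iv[[k]] <- step
    }
  }
  out <- tibble(
    genome = gnames,
    chrom = vapply(iv, `[[`, character(1), "chrom"),
    start = vapply(iv, `[[`, double(1), "start"),
    end = vapply(iv, `[[`, double(1), "end")
  )
  attr(out, "origin") <- request
  class(out) <- c("sr_zoom", class(out))
  out
}

#' Restrict a chain, markers and tracks to a zoom selection
#'
#' A block is kept only if both of its intervals overlap the selected window
#' of their respective genomes (a NOTAL block's single present side must
#' overlap); kept blocks are coordinate-clipped to the windows. Markers are
#' kept when they overlap their genome's window; tracks are re-binned over
#' the first genome's selected interval only.
#'
#' @param chain An `sr_chain`.
#' @param markers Marker tibble from [parse_markers()], or `NULL`.
#' @param tracks List of [track_spec()] objects, or `NULL`.
#' @param selection An `sr_zoom` from [propagate_region()].
#' @return A list with elements `chain` (blocks filtered and clipped),
#'   `markers` (filtered), `tracks` (list of binned track tibbles over the
#'   selected window) and `selection`.
#' @export
clip_to_selection <- function(chain, markers = NULL, tracks = NULL, selection) {
  stopifnot(inherits(chain, "sr_chain"), inherits(selection, "sr_zoom"))
  win <- function(g) {
    row <- selection[selection$genome == g, ]
    if (!nrow(row)) abort(paste0("selection lacks genome ", g))
    list(chrom = row$chrom[[1]], start = row$start[[1]], end = row$end[[1]])
  }
  clipped <- purrr::map(chain$comparisons, function(cmp) {
    wr <- win(cmp$ref_genome); wq <- win(cmp$qry_genome)
    b <- cmp$blocks
    ref_ok <- !is.na(b$ref_chrom) & b$ref_chrom == wr$chrom &
      b$ref_start <= wr$end & b$ref_end >= wr$start
    qry_ok <- !is.na(b$qry_chrom) & b$qry_chrom == wq$chrom &
      b$qry_start <= wq$end & b$qry_end >= wq$start
    keep <- ifelse(b$btype == "NOTAL",
                   (is.na(b$ref_chrom) | ref_ok) &
                     (is.na(b$qry_chrom) | qry_ok) &
                     !(is.na(b$ref_chrom) & is.na(b$qry_chrom)),
                   ref_ok & qry_ok)
    b <- b[keep, , drop = FALSE]
    b$ref_start <- pmax(b$ref_start, wr$start)
    b$ref_end <- pmin(b$ref_end, wr$end)
    b$qry_start <- pmax(b$qry_start, wq$start)
    b$qry_end <- pmin(b$qry_end, wq$end)
    pairwise_comparison(cmp$ref_genome, cmp$qry_genome, b)
  })
  new_chain <- structure(list(genomes = chain$genomes, comparisons = clipped),
                         class = "sr_chain")
  n_in <- sum(vapply(chain$comparisons, function(x) nrow(x$blocks), double(1)))
  n_out <- sum(vapply(clipped, function(x) nrow(x$blocks), double(1)))
  inform(paste0("zoom filter retained ", n_out, " of ", n_in, " blocks"))

  new_markers <- NULL
  if (!is.null(markers) && nrow(markers)) {
    keep <- vapply(seq_len(nrow(markers)), function(i) {
      w <- win(markers$genome[[i]])
      markers$chrom[[i]] == w$chrom &&
        markers$start[[i]] <= w$end && markers$end[[i]] >= w$start
    }, logical(1))
    new_markers <- markers[keep, , drop = FALSE]
  } else if (!is.null(markers)) {
    new_markers <- markers
  }

  new_tracks <- NULL
  if (!is.null(tracks) && length(tracks)) {
    w1 <- win(names(chain$genomes)[[1]])
    new_tracks <- purrr::map(tracks, function(sp) {
      bin_track_window(sp, w1)
    })
  }
  list(chain = new_chain, markers = new_markers, tracks = new_tracks,
       selection = selection)
}

# Re-bin one track over a single (chrom, start, end) window.
bin_track_window <- function(spec, window) {
  width <- window$end - window$start + 1
  nb <- ceiling(width / spec$bin_size)
  out <- tibble(
    track = spec$name,
    chrom = window$chrom,
    bin = seq_len(nb),
    bin_start = window$start + (seq_len(nb) - 1) * spec$bin_size,
    bin_end = pmin(window$start + seq_len(nb) * spec$bin_size - 1, window$end),
    value = 0
  )
  lines <- read_text_lines(spec$path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  chrom <- vapply(parts, `[[`, character(1), 1L)
  sel <- chrom == window$chrom
  if (!any(sel)) return(out)
  start1 <- as.double(vapply(parts, `[[`, character(1), 2L))[sel] + 1
  end1 <- as.double(vapply(parts, `[[`, character(1), 3L))[sel]
  if (spec$ttype == "bed_density") {
    mid <- floor((start1 + end1) / 2)
    inwin <- mid >= window$start & mid <= window$end
    b <- floor((mid[inwin] - window$start) / spec$bin_size) + 1
    if (length(b)) {
      cnt <- table(b)
      out$value[as.integer(names(cnt))] <- as.double(cnt)
    }
  } else {
    val <- as.double(vapply(parts, `[[`, character(1), 4L)[sel])
    for (j in seq_len(nb)) {
      bs <- out$bin_start[[j]]; be <- out$bin_end[[j]]
      w <- pmax(0, pmin(be, end1) - pmax(bs, start1) + 1)
      if (any(w > 0)) out$value[[j]] <- sum(val * w) / sum(w)
    }
  }
  out
}
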