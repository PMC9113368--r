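# formats_io: read and normalize every external file the tool consumes.
# Internal convention everywhere: coordinates are 1-based inclusive base pairs.
# BED/BEDPE (0-based half-open) are converted at the parser boundary.

#' Read chromosome names and lengths
#'
#' Chromosome sizes can come from a FASTA file (plain or gzip-compressed) or
#' from a two-column tab-separated table `name<TAB>length`.
#'
#' @param path Path to a FASTA file or a two-column length table.
#' @param format_hint One of `"auto"`, `"fasta"`, `"table"`. With `"auto"` the
#'   format is decided by the file extension and, failing that, by whether the
#'   first non-empty line starts with `>`.
#' @return A tibble with columns `name` (character) and `length` (double),
#'   one row per chromosome, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("c1\t1000", "c2\t500"), tf)
#' read_chromosome_lengths(tf)
#' @export
read_chromosome_lengths <- function(path, format_hint = c("auto", "fasta", "table")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) {
    abort(paste0("chromosome length file not found: ", path))
  }
  fmt <- format_hint
  if (fmt == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    fmt <- if (ext %in% c("fa", "fasta", "fna", "fas")) "fasta" else "table"
    if (fmt == "table") {
      first <- read_text_lines(path, n = 1L)
      if (length(first) && startsWith(first[[1]], ">")) fmt <- "fasta"
    }
  }
  recs <- if (fmt == "fasta") read_fasta_lengths(path) else read_length_table(path)
  dup <- recs$name[duplicated(recs$name)]
  if (length(dup)) {
    abort(paste0("duplicate chromosome name in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!nrow(recs)) abort(paste0("no chromosomes found in ", path))
  if (any(recs$length < 1)) {
    abort(paste0("chromosome with non-positive length in ", path, ": ",
                 paste(recs$name[recs$length < 1], collapse = ", ")))
  }
  recs
}

# readLines that transparently handles gzip.
read_text_lines <- function(path, n = -1L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, n = n, warn = FALSE)
}

read_fasta_lengths <- function(path) {
  len <- Biostrings::fasta.seqlengths(path)
  # chromosome name = first whitespace-delimited token of the header
  tibble(name = sub("\\s.*$", "", names(len)), length = as.double(len))
}

read_length_table <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    abort(paste0("length table ", path, " line ", bad[[1]],
                 ": expected two tab-separated columns"))
  }
  name <- vapply(parts, `[[`, character(1), 1L)
  lenstr <- vapply(parts, `[[`, character(1), 2L)
  nonint <- which(!grepl("^[0-9]+$", lenstr))
  if (length(nonint)) {
    abort(paste0("length table ", path, " line ", nonint[[1]],
                 ": non-integer length '", lenstr[nonint[[1]]], "'"))
  }
  tibble(name = name, length = as.double(lenstr))
}

#' Parse a SyRI-dialect structural annotation file
#'
#' Reads the 12-column tab-separated output of SyRI-style genome comparison:
#' `ref_chrom, ref_start, ref_end, ref_seq, qry_seq, qry_chrom, qry_start,
#' qry_end, id, parent, type, copy_status` (`-` marks a missing field; the
#' sequence columns are ignored). Only top-level structural records are kept:
#' types SYN, INV, TRANS, INVTR, DUP, INVDP and NOTAL whose parent field is
#' `-`. Local/child records (SNPs, indels, alignment children, HDR, CPG, CPL,
#' TDM, ...) are dropped. Query intervals given with start > end are
#' normalized by swapping and flagged `inverted`.
#'
#' @param path Path to the annotation file (plain text or gzip).
#' @return A tibble of alignment blocks with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `qry_chrom`, `qry_start`, `qry_end`, `btype`, `source_id`,
#'   `inverted`. NOTAL records keep `NA` on their missing side.
#' @export
parse_syri_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  lines <- read_text_lines(path)
  keep_line <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep_line]
  lineno <- which(keep_line)
  if (!length(lines)) return(empty_blocks())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short)) {
    abort(paste0(path, " line ", lineno[short[[1]]],
                 ": expected 12 tab-separated columns, found ",
                 lengths(parts)[short[[1]]]))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  type <- col(11L)
  parent <- col(10L)
  keep <- parent == "-" & type %in% BLOCK_TYPES
  if (!any(keep)) return(empty_blocks())
  idx <- which(keep)
  num <- function(x, what) {
    v <- suppressWarnings(as.double(x))
    miss <- x %in% c("-", "")
    bad <- which(is.na(v) & !miss)
    if (length(bad)) {
      abort(paste0(path, " line ", lineno[idx[bad[[1]]]],
                   ": non-numeric ", what, " '", x[bad[[1]]], "'"))
    }
    v[miss] <- NA_real_
    v
  }
  chrcol <- function(x) ifelse(x == "-", NA_character_, x)
  blocks <- tibble(
    ref_chrom = chrcol(col(1L)[idx]),
    ref_start = num(col(2L)[idx], "ref_start"),
    ref_end = num(col(3L)[idx], "ref_end"),
    qry_chrom = chrcol(col(6L)[idx]),
    qry_start = num(col(7L)[idx], "qry_start"),
    qry_end = num(col(8L)[idx], "qry_end"),
    btype = type[idx],
    source_id = ifelse(col(9L)[idx] == "-", "", col(9L)[idx]),
    inverted = FALSE
  )
  normalize_blocks(blocks)
}

# Swap reversed query intervals, set the inverted flag, sanity-check intervals.
normalize_blocks <- function(blocks) {
  swap <- !is.na(blocks$qry_start) & !is.na(blocks$qry_end) &
    blocks$qry_start > blocks$qry_end
  if (any(swap)) {
    tmp <- blocks$qry_start[swap]
    blocks$qry_start[swap] <- blocks$qry_end[swap]
    blocks$qry_end[swap] <- tmp
  }
  blocks$inverted <- swap | blocks$btype %in% INVERTED_TYPES
  bad <- !is.na(blocks$ref_start) & !is.na(blocks$ref_end) &
    blocks$ref_start > blocks$ref_end
  if (any(bad)) {
    abort(paste0("reference interval with start > end in record ",
                 blocks$source_id[which(bad)[1]]))
  }
  blocks
}

#' Parse a BEDPE structural annotation file
#'
#' BEDPE carries two intervals per line (`chrom1 start1 end1 chrom2 start2
#' end2`, 0-based half-open) plus, in this dialect, a seventh column holding
#' the annotation type. Coordinates are converted to the internal 1-based
#' inclusive convention (`start + 1`, `end` unchanged) and the type token is
#' matched case-insensitively against SYN, INV, TRANS, INVTR, DUP, INVDP,
#' NOTAL.
#'
#' @param path Path to the BEDPE file (>= 7 tab-separated columns).
#' @return A tibble of alignment blocks (same shape as [parse_syri_tsv()]).
#' @export
parse_bedpe <- function(path) {
  if (!file.exists(path)) abort(paste0("BEDPE file not found: ", path))
  lines <- read_text_lines(path)
  keep_line <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep_line]
  lineno <- which(keep_line)
  if (!length(lines)) return(empty_blocks())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 7L)
  if (length(short)) {
    abort(paste0(path, " line ", lineno[short[[1]]],
                 ": BEDPE needs >= 7 tab-separated columns"))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  type <- toupper(col(7L))
  unknown <- which(!type %in% BLOCK_TYPES)
  if (length(unknown)) {
    abort(paste0(path, " line ", lineno[unknown[[1]]],
                 ": unknown annotation type '", col(7L)[unknown[[1]]],
                 "'; allowed: ", paste(BLOCK_TYPES, collapse = ", ")))
  }
  num <- function(i, what) {
    x <- col(i)
    v <- suppressWarnings(as.double(x))
    miss <- x %in% c("-", ".", "")
    bad <- which(is.na(v) & !miss)
    if (length(bad)) {
      abort(paste0(path, " line ", lineno[bad[[1]]], ": non-numeric ", what))
    }
    v[miss] <- NA_real_
    v
  }
  s1 <- num(2L, "start1"); e1 <- num(3L, "end1")
  s2 <- num(5L, "start2"); e2 <- num(6L, "end2")
  degen <- which(e1 <= s1 | e2 <= s2)
  if (length(degen)) {
    abort(paste0(path, " line ", lineno[degen[[1]]],
                 ": end must exceed start in 0-based half-open BEDPE"))
  }
  id <- vapply(parts, function(p) if (length(p) >= 8L) p[[8L]] else "",
               character(1))
  blocks <- tibble(
    ref_chrom = ifelse(col(1L) %in% c("-", "."), NA_character_, col(1L)),
    ref_start = s1 + 1, ref_end = e1,
    qry_chrom = ifelse(col(4L) %in% c("-", "."), NA_character_, col(4L)),
    qry_start = s2 + 1, qry_end = e2,
    btype = type,
    source_id = ifelse(is.na(id) | id %in% c("-", "."), "", id),
    inverted = FALSE
  )
  normalize_blocks(blocks)
}

MARKER_DEFAULTS <- list(mt = "v", mc = "black", ms = 3, tt = "", tp = "top")

#' Parse a marker BED file
#'
#' Markers highlight predefined loci (genes, transposable elements, genomic
#' markers, ...) on any genome. The format is BED3 plus a fourth column naming
#' the genome and an optional fifth column of semicolon-separated `key:value`
#' display attributes: `mt` glyph, `mc` colour, `ms` size, `tt` label text,
#' `tp` label position. Unrecognized keys trigger a warning and are ignored.
#'
#' @param path Path to the marker BED file.
#' @param genome_names Character vector of configured genome names; a marker
#'   naming an unknown genome is a hard error.
#' @return A tibble with columns `genome`, `chrom`, `start`, `end` (1-based
#'   inclusive), `label`, `mt`, `mc`, `ms`, `tp`.
#' @export
parse_markers <- function(path, genome_names) {
  if (!file.exists(path)) abort(paste0("marker file not found: ", path))
  lines <- read_text_lines(path)
  keep_line <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep_line]
  lineno <- which(keep_line)
  if (!length(lines)) return(empty_markers())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 4L)
  if (length(short)) {
    abort(paste0(path, " line ", lineno[short[[1]]],
                 ": marker BED needs chrom, start, end, genome"))
  }
  col <- function(i) vapply(parts, function(p) if (length(p) >= i) p[[i]] else "", character(1))
  genome <- col(4L)
  badg <- which(!genome %in% genome_names)
  if (length(badg)) {
    abort(paste0(path, " line ", lineno[badg[[1]]], ": genome '",
                 genome[badg[[1]]], "' is not configured (known: ",
                 paste(genome_names, collapse = ", "), ")"))
  }
  attrs <- lapply(col(5L), parse_attr_string, defaults = MARKER_DEFAULTS,
                  context = path)
  tibble(
    genome = genome,
    chrom = col(1L),
    start = as.double(col(2L)) + 1,
    end = as.double(col(3L)),
    label = vapply(attrs, function(a) a$tt, character(1)),
    mt = vapply(attrs, function(a) a$mt, character(1)),
    mc = vapply(attrs, function(a) a$mc, character(1)),
    ms = vapply(attrs, function(a) as.double(a$ms), double(1)),
    tp = vapply(attrs, function(a) a$tp, character(1))
  )
}

empty_markers <- function() {
  tibble(genome = character(), chrom = character(), start = double(),
         end = double(), label = character(), mt = character(),
         mc = character(), ms = double(), tp = character())
}

# "k1:v1;k2:v2" -> defaults overridden by recognized keys; unknown keys warn.
parse_attr_string <- function(s, defaults, context = "") {
  out <- defaults
  if (is.na(s) || !nzchar(s)) return(out)
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    if (!nzchar(kv)) next
    m <- regexpr(":", kv, fixed = TRUE)
    if (m < 0) {
      warn(paste0(context, ": malformed attribute '", kv, "' ignored"))
      next
    }
    key <- substr(kv, 1, m - 1)
    val <- substr(kv, m + 1, nchar(kv))
    if (!key %in% names(defaults)) {
      warn(paste0(context, ": unknown attribute key '", key, "' ignored"))
      next
    }
    out[[key]] <- val
  }
  out
}

#' Describe a feature track
#'
#' A track shows the distribution of a genomic feature (genes, SNP density,
#' read coverage, ...) along the first genome's chromosomes as a binned
#' histogram. `bed_density` tracks count feature midpoints per bin from a BED
#' file; `bedgraph_value` tracks average bedGraph interval values per bin,
#' weighted by overlap length.
#'
#' @param path Source file (BED or bedGraph).
#' @param name Display label; defaults to the file name.
#' @param ttype `"bed_density"` or `"bedgraph_value"`; by default inferred
#'   from the extension (`.bedgraph`/`.bg` means values, anything else
#'   density).
#' @param bin_size Bin width in base pairs (default 100000).
#' @param attributes Named list of display overrides (e.g. `tc` colour).
#' @return A `track_spec` list.
#' @export
track_spec <- function(path, name = basename(path), ttype = NULL,
                       bin_size = 1e5, attributes = list()) {
  if (is.null(ttype)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    ttype <- if (ext %in% c("bedgraph", "bg")) "bedgraph_value" else "bed_density"
  }
  if (!ttype %in% c("bed_density", "bedgraph_value")) {
    abort(paste0("unknown track type '", ttype, "'"))
  }
  bin_size <- as.double(bin_size)
  if (is.na(bin_size) || bin_size < 1) abort("bin_size must be >= 1")
  structure(list(path = path, name = name, ttype = ttype,
                 bin_size = bin_size, attributes = attributes),
            class = "track_spec")
}

#' Bin a feature track along chromosomes
#'
#' @param spec A [track_spec()].
#' @param chromosomes Tibble of `name`, `length` for the coordinate genome
#'   (genome 1 of the chain).
#' @return A tibble with one row per bin: `track`, `chrom`, `bin`,
#'   `bin_start`, `bin_end` (1-based inclusive), `value`. Every chromosome
#'   gets `ceiling(length / bin_size)` bins; empty bins hold 0.
#' @export
load_track_values <- function(spec, chromosomes) {
  stopifnot(inherits(spec, "track_spec"))
  if (!file.exists(spec$path)) abort(paste0("track file not found: ", spec$path))
  lines <- read_text_lines(spec$path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol_needed <- if (spec$ttype == "bedgraph_value") 4L else 3L
  short <- which(lengths(parts) < ncol_needed)
  if (length(short)) {
    abort(paste0(spec$path, ": line with fewer than ", ncol_needed, " columns"))
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start0 <- as.double(vapply(parts, `[[`, character(1), 2L))
  end0 <- as.double(vapply(parts, `[[`, character(1), 3L))
  known <- chrom %in% chromosomes$name
  if (any(!known)) {
    warn(paste0(spec$path, ": skipping ", sum(!known),
                " record(s) on chromosome(s) absent from the coordinate genome: ",
                paste(unique(chrom[!known]), collapse = ", ")))
  }
  chrom <- chrom[known]; start0 <- start0[known]; end0 <- end0[known]
  bins <- tidyr::crossing(chrom = chromosomes$name) %>%
    left_join(chromosomes, by = c(chrom = "name")) %>%
    mutate(nbins = ceiling(.data$length / spec$bin_size)) %>%
    tidyr::uncount(.data$nbins, .id = "bin") %>%
    mutate(
      bin_start = (.data$bin - 1) * spec$bin_size + 1,
      bin_end = pmin(.data$bin * spec$bin_size, .data$length),
      value = 0
    ) %>%
    select("chrom", "bin", "bin_start", "bin_end", "value")
  if (length(chrom)) {
    if (spec$ttype == "bed_density") {
      # midpoint (1-based) of each feature decides its bin
      mid <- floor((start0 + 1 + end0) / 2)
      b <- floor((mid - 1) / spec$bin_size) + 1
      cnt <- tibble(chrom = chrom, bin = b) %>% count(.data$chrom, .data$bin)
      bins <- bins %>%
        left_join(cnt, by = c("chrom", "bin")) %>%
        mutate(value = ifelse(is.na(.data$n), 0, as.double(.data$n))) %>%
        select(-"n")
    } else {
      val <- as.double(vapply(parts, `[[`, character(1), 4L)[known])
      ivs <- tibble(chrom = chrom, start = start0 + 1, end = end0, val = val)
      ov <- bins %>%
        left_join(ivs, by = "chrom", relationship = "many-to-many") %>%
        mutate(w = pmax(0, pmin(.data$bin_end, .data$end) -
                          pmax(.data$bin_start, .data$start) + 1)) %>%
        filter(.data$w > 0) %>%
        group_by(.data$chrom, .data$bin) %>%
        summarise(wval = sum(.data$val * .data$w) / sum(.data$w),
                  .groups = "drop")
      bins <- bins %>%
        left_join(ov, by = c("chrom", "bin")) %>%
        mutate(value = ifelse(is.na(.data$wval), 0, .data$wval)) %>%
        select(-"wval")
    }
  }
  bins %>% mutate(track = spec$name, .before = 1)
}

#' Strip small variants from a SyRI-dialect file
#'
#' Removing SNP, INS and DEL records shrinks input files drastically and
#' speeds up parsing; structural records are untouched and row order is
#' preserved.
#'
#' @param path_in Input SyRI-dialect file.
#' @param path_out Output path (overwritten).
#' @return Invisibly, the number of removed records.
#' @export
filter_small_variants <- function(path_in, path_out) {
  if (!file.exists(path_in)) abort(paste0("annotation file not found: ", path_in))
  lines <- read_text_lines(path_in)
  content <- nzchar(lines) & !startsWith(lines, "#")
  parts <- strsplit(lines[content], "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short)) {
    abort(paste0(path_in, " line ", which(content)[short[[1]]],
                 ": expected 12 tab-separated columns"))
  }
  type <- vapply(parts, `[[`, character(1), 11L)
  drop <- logical(length(lines))
  drop[content] <- type %in% SMALL_VARIANT_TYPES
  writeLines(lines[!drop], path_out)
  invisible(sum(drop))
}
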