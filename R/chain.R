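# model_validation: assemble genomes and pairwise comparisons into a
# validated chain and enforce mutual consistency before any computation.
#
# The only supported topology is a path: genome 1 vs genome 2, genome 2 vs
# genome 3, and so on. Comparison k always has genomes[k] on the reference
# side and genomes[k + 1] on the query side.

#' Construct a genome specification
#'
#' @param name Genome identifier, unique across the run.
#' @param chromosomes Tibble of `name`, `length` as returned by
#'   [read_chromosome_lengths()].
#' @param display Named list of display attributes (`lc` line colour, `lw`
#'   line width, ...).
#' @return An `sr_genome` object.
#' @export
genome_spec <- function(name, chromosomes, display = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("genome name must be a single non-empty string")
  }
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (!nrow(chromosomes)) abort(paste0("genome ", name, " has no chromosomes"))
  if (anyDuplicated(chromosomes$name)) {
    abort(paste0("genome ", name, " has duplicate chromosome names"))
  }
  structure(list(name = name,
                 chromosomes = tibble::as_tibble(chromosomes[c("name", "length")]),
                 display = display),
            class = "sr_genome")
}

#' Construct a pairwise comparison
#'
#' @param ref_genome,qry_genome Names of the reference-side and query-side
#'   genomes (must differ).
#' @param blocks Tibble of alignment blocks from [parse_syri_tsv()] or
#'   [parse_bedpe()].
#' @return An `sr_comparison` object.
#' @export
pairwise_comparison <- function(ref_genome, qry_genome, blocks) {
  if (identical(ref_genome, qry_genome)) {
    abort("a comparison must link two distinct genomes")
  }
  stopifnot(is.data.frame(blocks))
  structure(list(ref_genome = ref_genome, qry_genome = qry_genome,
                 blocks = tibble::as_tibble(blocks)),
            class = "sr_comparison")
}

#' Build and validate a comparison chain
#'
#' Checks, before any downstream computation, that the assemblies and the
#' structural annotation are mutually consistent: N genomes need exactly
#' N - 1 comparisons in chain order, every chromosome named in a comparison
#' must exist in its genome (exact, case-sensitive match), and every interval
#' must lie within its chromosome's declared length. All violations are
#' collected and reported together so input files can be fixed in one pass.
#'
#' @param genomes List of [genome_spec()] objects in plotting order (top row
#'   first).
#' @param comparisons List of [pairwise_comparison()] objects; comparison k
#'   must link genome k (reference side) to genome k + 1 (query side).
#' @return An `sr_chain` object.
#' @export
build_chain <- function(genomes, comparisons) {
  if (inherits(genomes, "sr_genome")) genomes <- list(genomes)
  if (inherits(comparisons, "sr_comparison")) comparisons <- list(comparisons)
  stopifnot(all(vapply(genomes, inherits, logical(1), "sr_genome")),
            all(vapply(comparisons, inherits, logical(1), "sr_comparison")))
  n <- length(genomes)
  if (n < 2L) abort("a chain needs at least two genomes")
  if (length(comparisons) != n - 1L) {
    abort(paste0(n, " genomes require ", n - 1L, " pairwise comparisons, got ",
                 length(comparisons)))
  }
  gnames <- vapply(genomes, `[[`, character(1), "name")
  if (anyDuplicated(gnames)) {
    abort(paste0("duplicate genome name: ",
                 paste(unique(gnames[duplicated(gnames)]), collapse = ", ")))
  }
  names(genomes) <- gnames

  problems <- character()
  for (k in seq_len(n - 1L)) {
    cmp <- comparisons[[k]]
    if (!identical(cmp$ref_genome, gnames[[k]]) ||
        !identical(cmp$qry_genome, gnames[[k + 1L]])) {
      problems <- c(problems, paste0(
        "comparison ", k, " links ", cmp$ref_genome, " vs ", cmp$qry_genome,
        " but the chain order requires ", gnames[[k]], " vs ", gnames[[k + 1L]]))
      next
    }
    problems <- c(problems,
                  check_comparison_side(cmp$blocks, genomes[[k]], "ref", k),
                  check_comparison_side(cmp$blocks, genomes[[k + 1L]], "qry", k))
  }
  if (length(problems)) {
    abort(paste0("chain validation failed:\n", paste0("  - ", problems, collapse = "\n")))
  }
  structure(list(genomes = genomes, comparisons = comparisons),
            class = "sr_chain")
}

# Collect (not throw) violations for one side of one comparison.
check_comparison_side <- function(blocks, genome, side, k) {
  chrom <- blocks[[paste0(side, "_chrom")]]
  start <- blocks[[paste0(side, "_start")]]
  end <- blocks[[paste0(side, "_end")]]
  id <- blocks$source_id
  present <- !is.na(chrom)  # NOTAL records may have one empty side
  problems <- character()
  unknown <- unique(chrom[present & !chrom %in% genome$chromosomes$name])
  if (length(unknown)) {
    problems <- c(problems, paste0(
      "comparison ", k, ": chromosome(s) ", paste(unknown, collapse = ", "),
      " not present in genome ", genome$name))
  }
  len <- genome$chromosomes$length[match(chrom, genome$chromosomes$name)]
  oob <- which(present & !is.na(len) &
                 (start < 1 | end > len | is.na(start) | is.na(end)))
  if (length(oob)) {
    ex <- oob[[1]]
    problems <- c(problems, paste0(
      "comparison ", k, ": ", length(oob), " block(s) outside chromosome ",
      "bounds in genome ", genome$name, ", e.g. record '", id[ex], "' ",
      chrom[ex], ":", start[ex], "-", end[ex], " on a ", len[ex],
      " bp chromosome"))
  }
  problems
}

#' Per-comparison block counts by annotation type
#'
#' @param chain An `sr_chain`.
#' @return A tibble with columns `comparison` (label "ref vs qry"), `btype`,
#'   `n`; absent types appear with n = 0 so the counts always partition the
#'   block list.
#' @export
summarize_chain <- function(chain) {
  stopifnot(inherits(chain, "sr_chain"))
  purrr::imap_dfr(chain$comparisons, function(cmp, k) {
    tibble(comparison = paste(cmp$ref_genome, "vs", cmp$qry_genome),
           btype = factor(cmp$blocks$btype, levels = BLOCK_TYPES)) %>%
      count(.data$comparison, .data$btype, .drop = FALSE) %>%
      mutate(btype = as.character(.data$btype))
  })
}

#' Read a genomes configuration table
#'
#' Tab-separated file with columns `path`, `name`, `tags`; `tags` is an
#' optional semicolon-separated `key:value` display map (`lc` line colour,
#' `lw` line width).
#'
#' @param path Path to the config file.
#' @return A list of [genome_spec()] objects in file order.
#' @export
read_genomes_config <- function(path) {
  if (!file.exists(path)) abort(paste0("genomes config not found: ", path))
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort(paste0("genomes config is empty: ", path))
  purrr::map(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      abort(paste0(path, ": each line needs at least path<TAB>name"))
    }
    gpath <- f[[1]]
    if (!file.exists(gpath) && !startsWith(gpath, "/")) {
      candidate <- file.path(dirname(path), gpath)
      if (file.exists(candidate)) gpath <- candidate
    }
    display <- if (length(f) >= 3L && nzchar(f[[3]])) {
      parse_attr_string(f[[3]], defaults = list(lc = "dimgrey", lw = "1"),
                        context = path)
    } else {
      list(lc = "dimgrey", lw = "1")
    }
    genome_spec(f[[2]], read_chromosome_lengths(gpath), display = display)
  })
}

#' @export
print.sr_chain <- function(x, ...) {
  cat("<sr_chain> ", length(x$genomes), " genomes: ",
      paste(names(x$genomes), collapse = " - "), "\n", sep = "")
  s <- summarize_chain(x) %>% filter(.data$n > 0)
  for (cmp in unique(s$comparison)) {
    rows <- s[s$comparison == cmp, ]
    cat("  ", cmp, ": ",
        paste0(rows$btype, "=", rows$n, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a comparison chain into one row per alignment block
#'
#' @param x An `sr_chain`.
#' @param ... Unused.
#' @return A tibble of all blocks with `ref_genome`/`qry_genome` columns
#'   prepended.
#' @export
tidy.sr_chain <- function(x, ...) {
  purrr::map_dfr(x$comparisons, function(cmp) {
    cmp$blocks %>%
      mutate(ref_genome = cmp$ref_genome, qry_genome = cmp$qry_genome,
             .before = 1)
  })
}

#' One-row summary of a comparison chain
#'
#' @param x An `sr_chain`.
#' @param ... Unused.
#' @export
glance.sr_chain <- function(x, ...) {
  blocks <- tidy(x)
  tibble(
    n_genomes = length(x$genomes),
    n_comparisons = length(x$comparisons),
    n_chromosomes = sum(vapply(x$genomes, function(g) nrow(g$chromosomes),
                               integer(1))),
    n_blocks = nrow(blocks),
    n_syn = sum(blocks$btype == "SYN"),
    n_sr = sum(blocks$btype %in% setdiff(RIBBON_TYPES, "SYN")),
    n_notal = sum(blocks$btype == "NOTAL")
  )
}
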