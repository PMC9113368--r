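# homology: group chromosomes across all genomes into homologous sets using
# shared syntenic length in the pairwise comparisons.

#' Match homologous chromosomes between the two sides of one comparison
#'
#' Builds the matrix of total syntenic base pairs (reference side) between
#' every reference chromosome and every query chromosome, then assigns pairs
#' greedily by descending weight, one-to-one, breaking ties lexicographically
#' on (reference name, query name). Chromosome-level synteny matrices are
#' strongly diagonal-dominant in practice, where greedy assignment coincides
#' with the optimal one and is trivially auditable.
#'
#' @param comparison An [pairwise_comparison()] object (or any list with a
#'   `blocks` tibble).
#' @return A tibble with columns `ref_chrom`, `qry_chrom`, `syn_bp`, one row
#'   per matched pair, ordered by descending `syn_bp`. Chromosomes with zero
#'   syntenic bases stay unmatched and are reported via a message.
#' @export
pair_homology <- function(comparison) {
  blocks <- comparison$blocks
  syn <- blocks %>%
    filter(.data$btype == "SYN",
           !is.na(.data$ref_chrom), !is.na(.data$qry_chrom))
  if (!nrow(syn)) {
    abort(paste0("no syntenic backbone: comparison ",
                 comparison$ref_genome %||% "?", " vs ",
                 comparison$qry_genome %||% "?", " has no SYN blocks"))
  }
  weights <- syn %>%
    group_by(.data$ref_chrom, .data$qry_chrom) %>%
    summarise(syn_bp = sum(.data$ref_end - .data$ref_start + 1),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$syn_bp), .data$ref_chrom, .data$qry_chrom)
  used_ref <- character(); used_qry <- character()
  pick <- logical(nrow(weights))
  for (i in seq_len(nrow(weights))) {
    r <- weights$ref_chrom[[i]]; q <- weights$qry_chrom[[i]]
    if (r %in% used_ref || q %in% used_qry) next
    pick[[i]] <- TRUE
    used_ref <- c(used_ref, r); used_qry <- c(used_qry, q)
  }
  res <- weights[pick, ]
  all_ref <- unique(c(blocks$ref_chrom, syn$ref_chrom))
  all_qry <- unique(c(blocks$qry_chrom, syn$qry_chrom))
  loose <- c(setdiff(all_ref[!is.na(all_ref)], res$ref_chrom),
             setdiff(all_qry[!is.na(all_qry)], res$qry_chrom))
  if (length(loose)) {
    inform(paste0("pair_homology: ", length(loose),
                  " chromosome(s) without a syntenic match: ",
                  paste(loose, collapse = ", ")))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group homologous chromosomes across the whole chain
#'
#' Composes the per-pair matchings along the chain: each chromosome of
#' genome 1 seeds one group, which is extended genome by genome through the
#' pairwise matches. A chromosome matched in pair k but absent from pair
#' k + 1's synteny truncates its group with a warning. Chromosomes of later
#' genomes that end up in no group become singleton groups (appended after
#' the seeded groups, in genome order) so that every chromosome of every
#' genome belongs to exactly one group.
#'
#' @param chain An `sr_chain`.
#' @param chrom_order Optional character vector of genome-1 chromosome names
#'   giving the group order (an explicit order file, one name per line, read
#'   with `readLines()`); unlisted genome-1 chromosomes follow in their
#'   native order.
#' @return A tibble with columns `order_index`, `genome`, `chrom`; one row
#'   per group member.
#' @export
chain_homology <- function(chain, chrom_order = NULL) {
  stopifnot(inherits(chain, "sr_chain"))
  gnames <- names(chain$genomes)
  n <- length(gnames)
  matchings <- purrr::map(chain$comparisons, pair_homology)

  seeds <- chain$genomes[[1]]$chromosomes$name
  if (!is.null(chrom_order)) {
    unknown <- setdiff(chrom_order, seeds)
    if (length(unknown)) {
      abort(paste0("chromosome order file names unknown genome-1 chromosome(s): ",
                   paste(unknown, collapse = ", ")))
    }
    seeds <- c(chrom_order, setdiff(seeds, chrom_order))
  }

  groups <- purrr::imap_dfr(seeds, function(c1, i) {
    members <- tibble(genome = gnames[[1]], chrom = c1)
    current <- c1
    for (k in seq_len(n - 1L)) {
      m <- matchings[[k]]
      hit <- m$qry_chrom[match(current, m$ref_chrom)]
      if (is.na(hit)) {
        warn(paste0("homology group of ", c1, " truncated at ",
                    gnames[[k]], ": ", current,
                    " has no syntenic match in ", gnames[[k + 1L]]))
        break
      }
      members <- bind_rows(members,
                           tibble(genome = gnames[[k + 1L]], chrom = hit))
      current <- hit
    }
    members$order_index <- i
    members
  })

  # singleton groups for chromosomes not reached from genome 1
  next_idx <- max(groups$order_index) + 1L
  extras <- list()
  for (g in gnames[-1]) {
    for (chrom in chain$genomes[[g]]$chromosomes$name) {
      placed <- any(groups$genome == g & groups$chrom == chrom)
      if (!placed) {
        inform(paste0("chromosome ", chrom, " of genome ", g,
                      " has no homolog across the chain; drawn as a ",
                      "singleton group"))
        extras[[length(extras) + 1L]] <-
          tibble(genome = g, chrom = chrom, order_index = next_idx)
        next_idx <- next_idx + 1L
      }
    }
  }
  out <- bind_rows(groups, bind_rows(extras)) %>%
    select("order_index", "genome", "chrom") %>%
    arrange(.data$order_index)
  class(out) <- c("sr_homology", class(out))
  out
}
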