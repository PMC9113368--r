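# Small programmatic builders shared across test files.

mk_block <- function(ref_chrom, ref_start, ref_end, qry_chrom, qry_start,
                     qry_end, btype = "SYN", source_id = "",
                     inverted = btype %in% c("INV", "INVTR", "INVDP")) {
  tibble::tibble(ref_chrom = ref_chrom, ref_start = ref_start,
                 ref_end = ref_end, qry_chrom = qry_chrom,
                 qry_start = qry_start, qry_end = qry_end, btype = btype,
                 source_id = source_id, inverted = inverted)
}

mk_genome <- function(name, chroms) {
  genome_spec(name, tibble::tibble(name = names(chroms),
                                   length = unname(chroms)))
}

# Two-genome identity chain on a single chromosome of length L.
identity_chain <- function(L = 1000, n_genomes = 2, chrom = "c1") {
  genomes <- lapply(seq_len(n_genomes), function(i) {
    mk_genome(paste0("g", i), stats::setNames(L, chrom))
  })
  comps <- lapply(seq_len(n_genomes - 1), function(k) {
    pairwise_comparison(paste0("g", k), paste0("g", k + 1),
                        mk_block(chrom, 1, L, chrom, 1, L, "SYN", "SYN1"))
  })
  build_chain(genomes, comps)
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Build an sr_chain straight from a generated fixture bundle (in-memory
# truth blocks, so parser behaviour does not leak into non-parser tests).
fixture_chain <- function(fx) {
  n <- length(fx$genomes)
  genomes <- lapply(names(fx$genomes), function(g) genome_spec(g, fx$genomes[[g]]))
  comps <- lapply(seq_len(n - 1), function(k) {
    pairwise_comparison(paste0("genome", k), paste0("genome", k + 1),
                        fx$blocks[[k]])
  })
  build_chain(genomes, comps)
}
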