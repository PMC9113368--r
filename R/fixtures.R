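# fixtures: deterministic synthetic genomes, pairwise annotation files,
# markers and tracks with planted ground truth, so every other module is
# testable without downloading anything.
#
# The emitted genomes are structurally simple by design: a syntenic backbone
# tiling each chromosome, with planted inversions, translocations and
# duplications at seeded-random, non-overlapping positions. Inversions are
# intra-chromosomal; translocations are inter-chromosomal whenever a genome
# has more than one chromosome (relocations of both kinds are annotated
# TRANS); duplications copy a region elsewhere on the homologous chromosome.

#' Describe a synthetic fixture
#'
#' @param n_genomes Number of genomes in the chain (>= 2).
#' @param chroms_per_genome Chromosomes per genome.
#' @param chrom_length Chromosome length in base pairs (genome 1; later
#'   genomes scale by `dilation` per step).
#' @param n_inversions,n_translocations,n_duplications Planted event counts
#'   per adjacent genome pair.
#' @param rename_chromosomes When `TRUE`, every genome uses its own
#'   chromosome naming style and a shuffled chromosome order, exercising
#'   homology grouping.
#' @param dilation Per-step coordinate scale factor (>= 1); a value of 2
#'   doubles every coordinate at each hop, exercising zoom interpolation.
#' @param seed Random seed; the whole bundle is a pure function of these
#'   parameters.
#' @param n_syn_breaks Extra random breakpoints per chromosome that fragment
#'   the syntenic backbone without changing it, to reach realistic block
#'   counts.
#' @param n_small_variants SNP/INS/DEL salt records added to the SyRI-dialect
#'   files (they must be invisible to all structural parsing).
#' @param with_fasta Also emit tiny all-`A` FASTA files (only lengths matter
#'   downstream).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genomes = 3, chroms_per_genome = 2,
                         chrom_length = 1e6, n_inversions = 2,
                         n_translocations = 1, n_duplications = 1,
                         rename_chromosomes = FALSE, dilation = 1,
                         seed = 1, n_syn_breaks = 0, n_small_variants = 0,
                         with_fasta = FALSE) {
  spec <- list(n_genomes = as.integer(n_genomes),
               chroms_per_genome = as.integer(chroms_per_genome),
               chrom_length = as.double(chrom_length),
               n_inversions = as.integer(n_inversions),
               n_translocations = as.integer(n_translocations),
               n_duplications = as.integer(n_duplications),
               rename_chromosomes = isTRUE(rename_chromosomes),
               dilation = as.double(dilation),
               seed = as.integer(seed),
               n_syn_breaks = as.integer(n_syn_breaks),
               n_small_variants = as.integer(n_small_variants),
               with_fasta = isTRUE(with_fasta))
  stopifnot(spec$n_genomes >= 2, spec$chroms_per_genome >= 1,
            spec$chrom_length >= 100, spec$dilation >= 1,
            spec$n_inversions >= 0, spec$n_translocations >= 0,
            spec$n_duplications >= 0, spec$n_syn_breaks >= 0,
            spec$n_small_variants >= 0)
  structure(spec, class = "fixture_spec")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

chrom_name <- function(style, k) {
  prefixes <- c("chr", "Chr", "c", "CHR_", "ctg", "scaffold_")
  paste0(prefixes[((style - 1) %% length(prefixes)) + 1], k)
}

# Sample n non-overlapping intervals with the given lengths inside [1, L],
# also avoiding `avoid` (2-column matrix of start,end). Errors when they
# cannot be placed.
place_intervals <- function(n, sizes, L, avoid = NULL) {
  placed <- if (is.null(avoid)) matrix(numeric(0), ncol = 2) else avoid
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:200) {
      s <- floor(runif(1, 2, L - sizes[i])) # keep 1 bp of backbone at each end
      e <- s + sizes[i] - 1
      if (e >= L) next
      if (!nrow(placed) ||
          all(e < placed[, 1] - 1 | s > placed[, 2] + 1)) {
        placed <- rbind(placed, c(s, e))
        out <- rbind(out, c(s, e))
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("fixture spec infeasible: planted events do not fit")
  }
  out
}

#' Generate a synthetic fixture bundle with planted truth
#'
#' Emits, under `dir`: per-genome length tables (and optional FASTAs), one
#' SyRI-dialect TSV and one equivalent BEDPE per adjacent pair, a genomes
#' config table, a marker BED, a density-track BED, and plain-text truth
#' tables. Re-parsing every emitted file reproduces the returned truth
#' exactly.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return A list with `files` (named paths), `genomes` (list of genome
#'   tibbles), `blocks` (list of per-pair truth block tibbles, in the
#'   normalized parser representation), `groups` (planted homology tibble),
#'   and `spec`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  C <- spec$chroms_per_genome
  N <- spec$n_genomes
  # feasibility: worst case all cutting events land on one chromosome
  n_cut <- spec$n_inversions + spec$n_translocations + spec$n_duplications
  if (n_cut * 0.05 * spec$chrom_length * 1.2 > 0.8 * spec$chrom_length) {
    abort("fixture spec infeasible: planted events do not fit the chromosome")
  }
  with_seed(spec$seed, generate_fixture_impl(spec, dir, C, N))
}

generate_fixture_impl <- function(spec, dir, C, N) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L1 <- spec$chrom_length

  # genome g, homology group h -> chromosome name, length, position in file
  glen <- function(g) round(L1 * spec$dilation^(g - 1))
  gname <- paste0("genome", seq_len(N))
  cname <- matrix("", nrow = N, ncol = C)
  order_of <- matrix(0L, nrow = N, ncol = C)  # position of group h in genome g
  for (g in seq_len(N)) {
    style <- if (spec$rename_chromosomes) g else 1L
    cname[g, ] <- vapply(seq_len(C), function(k) chrom_name(style, k),
                         character(1))
    order_of[g, ] <- if (spec$rename_chromosomes && g > 1L) {
      sample(C)
    } else {
      seq_len(C)
    }
  }

  files <- list()
  genomes <- list()
  for (g in seq_len(N)) {
    ord <- order(order_of[g, ])  # groups in file order
    tab <- tibble(name = cname[g, ord], length = rep(glen(g), C))
    path <- file.path(dir, paste0(gname[g], ".tsv"))
    writeLines(paste(tab$name, format(tab$length, scientific = FALSE,
                                      trim = TRUE), sep = "\t"), path)
    files[[paste0("lengths_", g)]] <- path
    genomes[[gname[g]]] <- tab
    if (spec$with_fasta) {
      fpath <- file.path(dir, paste0(gname[g], ".fa"))
      con <- file(fpath, "w")
      for (i in seq_len(C)) {
        writeLines(paste0(">", tab$name[i]), con)
        writeLines(strrep("A", tab$length[i]), con)
      }
      close(con)
      files[[paste0("fasta_", g)]] <- fpath
    }
  }

  groups <- purrr::map_dfr(seq_len(C), function(h) {
    tibble(order_index = h, genome = gname, chrom = cname[, h])
  }) %>% arrange(.data$order_index)

  blocks <- vector("list", N - 1L)
  for (p in seq_len(N - 1L)) {
    Lr <- glen(p); Lq <- glen(p + 1L)
    f <- function(x) {  # monotone coordinate map ref -> qry for this pair
      if (Lr == Lq) x else 1 + round((x - 1) * (Lq - 1) / (Lr - 1))
    }
    # assign each planted event a source chromosome (homology-group index)
    ev_types <- c(rep("INV", spec$n_inversions),
                  rep("TRANS", spec$n_translocations),
                  rep("DUP", spec$n_duplications))
    ev_chrom <- if (length(ev_types)) sample(C, length(ev_types),
                                             replace = TRUE) else integer(0)
    pair_blocks <- list()
    counters <- c(SYN = 0L, INV = 0L, TRANS = 0L, DUP = 0L)
    for (h in seq_len(C)) {
      idx <- which(ev_chrom == h)
      sizes <- if (length(idx)) {
        pmax(10, round(runif(length(idx), 0.01, 0.05) * Lr))
      } else {
        numeric(0)
      }
      iv <- place_intervals(length(idx), sizes, Lr)
      cut <- matrix(numeric(0), ncol = 2)
      for (j in seq_along(idx)) {
        ty <- ev_types[idx[j]]
        a <- iv[j, 1]; bnd <- iv[j, 2]
        counters[ty] <- counters[ty] + 1L
        id <- paste0(ty, counters[ty])
        if (ty == "INV") {
          pair_blocks[[length(pair_blocks) + 1L]] <- tibble(
            ref_chrom = cname[p, h], ref_start = a, ref_end = bnd,
            qry_chrom = cname[p + 1L, h], qry_start = f(a), qry_end = f(bnd),
            btype = "INV", source_id = id, inverted = TRUE)
          cut <- rbind(cut, c(a, bnd))
        } else if (ty == "TRANS") {
          h2 <- if (C > 1L) sample(setdiff(seq_len(C), h), 1L) else h
          len_q <- f(bnd) - f(a)
          qs <- floor(runif(1, 1, Lq - len_q))
          pair_blocks[[length(pair_blocks) + 1L]] <- tibble(
            ref_chrom = cname[p, h], ref_start = a, ref_end = bnd,
            qry_chrom = cname[p + 1L, h2], qry_start = qs,
            qry_end = qs + len_q, btype = "TRANS", source_id = id,
            inverted = FALSE)
          cut <- rbind(cut, c(a, bnd))
        } else { # DUP: extra copy elsewhere on the homologous chromosome
          len_q <- f(bnd) - f(a)
          qs <- floor(runif(1, 1, Lq - len_q))
          pair_blocks[[length(pair_blocks) + 1L]] <- tibble(
            ref_chrom = cname[p, h], ref_start = a, ref_end = bnd,
            qry_chrom = cname[p + 1L, h], qry_start = qs,
            qry_end = qs + len_q, btype = "DUP", source_id = id,
            inverted = FALSE)
          cut <- rbind(cut, c(a, bnd))
        }
      }
      # syntenic backbone tiles the complement of the cut intervals
      cut <- cut[order(cut[, 1]), , drop = FALSE]
      bounds <- c(1, as.vector(t(cut)), Lr)
      tiles <- matrix(bounds, ncol = 2, byrow = TRUE)
      tiles[, 1] <- ifelse(tiles[, 1] == 1, 1, tiles[, 1] + 1)
      tiles[-nrow(tiles), 2] <- tiles[-nrow(tiles), 2] - 1
      tiles <- tiles[tiles[, 2] >= tiles[, 1], , drop = FALSE]
      if (spec$n_syn_breaks > 0) {
        brk <- sort(unique(floor(runif(spec$n_syn_breaks, 2, Lr - 1))))
        pieces <- lapply(seq_len(nrow(tiles)), function(t_) {
          s <- tiles[t_, 1]; e <- tiles[t_, 2]
          cuts <- c(s - 1, brk[brk > s & brk < e], e)
          cbind(cuts[-length(cuts)] + 1, cuts[-1])
        })
        tiles <- do.call(rbind, pieces)
      }
      n_tiles <- nrow(tiles)
      if (n_tiles > 0) {
        ids <- counters[["SYN"]] + seq_len(n_tiles)
        counters["SYN"] <- counters[["SYN"]] + n_tiles
        pair_blocks[[length(pair_blocks) + 1L]] <- tibble(
          ref_chrom = cname[p, h], ref_start = tiles[, 1],
          ref_end = tiles[, 2],
          qry_chrom = cname[p + 1L, h], qry_start = f(tiles[, 1]),
          qry_end = f(tiles[, 2]), btype = "SYN",
          source_id = paste0("SYN", ids), inverted = FALSE)
      }
    }
    blocks[[p]] <- bind_rows(pair_blocks)
    files[[paste0("syri_", p)]] <-
      write_syri_fixture(blocks[[p]], spec$n_small_variants,
                         file.path(dir, sprintf("pair_%d_%d.syri.tsv",
                                                p, p + 1L)))
    files[[paste0("bedpe_", p)]] <-
      write_bedpe_fixture(blocks[[p]],
                          file.path(dir, sprintf("pair_%d_%d.bedpe",
                                                 p, p + 1L)))
  }

  # genomes config in chain order
  cfg_path <- file.path(dir, "genomes.tsv")
  writeLines(paste(paste0(gname, ".tsv"), gname, "lc:dimgrey;lw:1",
                   sep = "\t"), cfg_path)
  files[["genomes_config"]] <- cfg_path

  # markers: one labelled marker near the start of each genome-1 chromosome
  mpos <- pmin(1000, L1 - 1)
  marker_path <- file.path(dir, "markers.bed")
  writeLines(paste(cname[1, ], format(mpos - 1, scientific = FALSE),
                   format(mpos, scientific = FALSE), gname[1],
                   paste0("tt:locus_", seq_len(C), ";mc:red"),
                   sep = "\t"), marker_path)
  files[["markers"]] <- marker_path

  # density track: 20 features per genome-1 chromosome
  feat_start <- unlist(lapply(seq_len(C), function(h) {
    sort(floor(runif(20, 1, L1 - 10)))
  }))
  track_path <- file.path(dir, "track_features.bed")
  writeLines(paste(rep(cname[1, ], each = 20),
                   format(feat_start, scientific = FALSE, trim = TRUE),
                   format(feat_start + 10, scientific = FALSE, trim = TRUE),
                   sep = "\t"), track_path)
  files[["track"]] <- track_path

  # plain-text truth tables
  truth_blocks <- purrr::imap_dfr(blocks, function(b, p) {
    mutate(b, pair = p, .before = 1)
  })
  tb_path <- file.path(dir, "truth_blocks.tsv")
  utils::write.table(truth_blocks, tb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tg_path <- file.path(dir, "truth_groups.tsv")
  utils::write.table(groups, tg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files[["truth_blocks"]] <- tb_path
  files[["truth_groups"]] <- tg_path

  list(files = files, genomes = genomes, blocks = blocks, groups = groups,
       spec = spec)
}

# SyRI-dialect writer. Inversions are written with reversed query
# coordinates (start > end), the convention the parser must normalize.
write_syri_fixture <- function(blocks, n_small_variants, path) {
  fmtn <- function(x) format(x, scientific = FALSE, trim = TRUE)
  qs <- ifelse(blocks$inverted, blocks$qry_end, blocks$qry_start)
  qe <- ifelse(blocks$inverted, blocks$qry_start, blocks$qry_end)
  rows <- paste(blocks$ref_chrom, fmtn(blocks$ref_start),
                fmtn(blocks$ref_end), "-", "-", blocks$qry_chrom,
                fmtn(qs), fmtn(qe), blocks$source_id, "-", blocks$btype, "-",
                sep = "\t")
  if (n_small_variants > 0) {
    syn <- blocks[blocks$btype == "SYN", , drop = FALSE]
    host <- syn[sample(nrow(syn), n_small_variants, replace = TRUE), ]
    pos <- floor(runif(n_small_variants, host$ref_start, host$ref_end + 1))
    vtype <- sample(SMALL_VARIANT_TYPES, n_small_variants, replace = TRUE)
    salt <- paste(host$ref_chrom, fmtn(pos), fmtn(pos), "A", "T",
                  host$qry_chrom, fmtn(pos), fmtn(pos),
                  paste0(vtype, seq_len(n_small_variants)), host$source_id,
                  vtype, "-", sep = "\t")
    # interleave deterministically: salt rows follow their host block rows
    rows <- c(rows, salt)[order(c(seq_along(rows),
                                  match(host$source_id, blocks$source_id) + 0.5))]
  }
  writeLines(rows, path)
  path
}

write_bedpe_fixture <- function(blocks, path) {
  fmtn <- function(x) format(x, scientific = FALSE, trim = TRUE)
  rows <- paste(blocks$ref_chrom, fmtn(blocks$ref_start - 1),
                fmtn(blocks$ref_end), blocks$qry_chrom,
                fmtn(blocks$qry_start - 1), fmtn(blocks$qry_end),
                blocks$btype, blocks$source_id, sep = "\t")
  writeLines(rows, path)
  path
}

#' Brute-force per-base zoom mapping oracle
#'
#' Builds the explicit base-to-base correspondence implied by the SYN blocks
#' (the same within-block linear interpolation, applied to every base of the
#' region rather than just its endpoints) and returns the (min, max) of the
#' images. Intended for small comparisons in tests only.
#'
#' @param region List with `chrom`, `start`, `end` (source side).
#' @param blocks Block tibble of one comparison.
#' @param direction `"ref2qry"` or `"qry2ref"`.
#' @return `list(chrom, start, end)` or `NULL` when no base of the region is
#'   covered by a SYN block.
#' @export
oracle_map_region <- function(region, blocks,
                              direction = c("ref2qry", "qry2ref")) {
  direction <- match.arg(direction)
  src <- if (direction == "ref2qry") "ref" else "qry"
  tgt <- if (direction == "ref2qry") "qry" else "ref"
  syn <- blocks[blocks$btype == "SYN" &
                  !is.na(blocks[[paste0(src, "_chrom")]]) &
                  blocks[[paste0(src, "_chrom")]] == region$chrom, ,
                drop = FALSE]
  if (!nrow(syn)) return(NULL)
  images <- list()
  chroms <- character()
  for (i in seq_len(nrow(syn))) {
    ss <- syn[[paste0(src, "_start")]][[i]]
    se <- syn[[paste0(src, "_end")]][[i]]
    ts <- syn[[paste0(tgt, "_start")]][[i]]
    te <- syn[[paste0(tgt, "_end")]][[i]]
    lo <- max(ss, region$start); hi <- min(se, region$end)
    if (lo > hi) next
    p <- lo:hi
    off <- if (se > ss) floor((p - ss) * (te - ts) / (se - ss)) else 0
    img <- if (syn$inverted[[i]]) te - off else ts + off
    images[[length(images) + 1L]] <- img
    chroms <- c(chroms, rep(syn[[paste0(tgt, "_chrom")]][[i]], length(img)))
  }
  if (!length(images)) return(NULL)
  img <- unlist(images)
  best <- names(sort(table(chroms), decreasing = TRUE))[[1]]
  img <- img[chroms == best]
  list(chrom = best, start = min(img), end = max(img))
}
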