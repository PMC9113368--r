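test_that("endpoints map by within-block linear interpolation", {
  cmp <- list(blocks = mk_block("c1", 100, 200, "cA", 300, 400, "SYN", "s1"))
  r <- map_region_step(list(chrom = "c1", start = 150, end = 180), cmp)
  expect_equal(r, list(chrom = "cA", start = 350, end = 380))

  # a request equal to the block's source interval maps to its counterpart
  r2 <- map_region_step(list(chrom = "c1", start = 100, end = 200), cmp)
  expect_equal(r2, list(chrom = "cA", start = 300, end = 400))

  # identity comparison returns the request unchanged
  idcmp <- list(blocks = mk_block("c1", 1, 1000, "c1", 1, 1000, "SYN", "s"))
  expect_equal(map_region_step(list(chrom = "c1", start = 10, end = 20), idcmp),
               list(chrom = "c1", start = 10, end = 20))
})

test_that("inverted blocks and reverse direction map correctly", {
  inv <- list(blocks = mk_block("c1", 100, 199, "cA", 300, 399, "SYN", "s1",
                                inverted = TRUE))
  r <- map_region_step(list(chrom = "c1", start = 100, end = 109), inv)
  # start maps to the far end of the counterpart
  expect_equal(r, list(chrom = "cA", start = 390, end = 399))

  fwd <- list(blocks = mk_block("c1", 100, 200, "cA", 300, 400, "SYN", "s1"))
  back <- map_region_step(list(chrom = "cA", start = 350, end = 380), fwd,
                          direction = "qry2ref")
  expect_equal(back, list(chrom = "c1", start = 150, end = 180))
})

test_that("gap endpoints snap to the nearest adjacent block edge", {
  cmp <- list(blocks = dplyr::bind_rows(
    mk_block("c1", 1, 100, "cA", 1, 100, "SYN", "s1"),
    mk_block("c1", 201, 300, "cA", 201, 300, "SYN", "s2")))
  # start endpoint falls in the 101..200 gap
  r <- map_region_step(list(chrom = "c1", start = 150, end = 250), cmp)
  expect_equal(r, list(chrom = "cA", start = 201, end = 250))
  # end endpoint in the gap snaps back to the left block's counterpart end
  r2 <- map_region_step(list(chrom = "c1", start = 50, end = 150), cmp)
  expect_equal(r2, list(chrom = "cA", start = 50, end = 100))
  # region fully inside the gap has no syntenic anchor at all
  expect_error(map_region_step(list(chrom = "c1", start = 120, end = 180), cmp),
               "dead-ends")
})

test_that("endpoint mapping equals the per-base oracle on random backbones", {
  n_agree <- 0
  for (seed in 1:10) {
    fx <- generate_fixture(fixture_spec(n_genomes = 2, chroms_per_genome = 1,
                                        chrom_length = 8000, n_inversions = 1,
                                        n_translocations = 0,
                                        n_duplications = 1,
                                        n_syn_breaks = 5, seed = seed))
    blocks <- fx$blocks[[1]]
    cmp <- list(blocks = blocks)
    chrom <- blocks$ref_chrom[[1]]
    set.seed(seed + 1000)
    for (probe in 1:20) {
      s <- sample(7000, 1); e <- s + sample(900, 1)
      o <- oracle_map_region(list(chrom = chrom, start = s, end = e), blocks)
      if (is.null(o)) {
        expect_error(map_region_step(list(chrom = chrom, start = s, end = e),
                                     cmp), "dead-ends")
      } else {
        m <- map_region_step(list(chrom = chrom, start = s, end = e), cmp)
        expect_identical(m, o)
        n_agree <- n_agree + 1
      }
    }
  }
  expect_gt(n_agree, 150)
})

test_that("propagation covers every genome from any origin", {
  ch <- identity_chain(L = 1000, n_genomes = 3)
  sel <- propagate_region(region_request("g2", "c1", 10, 20), ch)
  expect_equal(nrow(sel), 3)
  expect_true(all(sel$chrom == "c1"))
  expect_true(all(sel$start == 10 & sel$end == 20))

  # dilation fixture: the interval width doubles per hop
  fx <- generate_fixture(fixture_spec(n_genomes = 4, chroms_per_genome = 1,
                                      chrom_length = 8000, n_inversions = 0,
                                      n_translocations = 0,
                                      n_duplications = 0, dilation = 2,
                                      seed = 2))
  ch2 <- fixture_chain(fx)
  sel2 <- propagate_region(region_request("genome1", "chr1", 1001, 2000), ch2)
  w <- sel2$end - sel2$start + 1
  expect_equal(w[2] / w[1], 2, tolerance = 2e-3)
  expect_equal(w[3] / w[2], 2, tolerance = 2e-3)
  expect_equal(w[4] / w[3], 2, tolerance = 2e-3)
})

test_that("requests are validated against the chain", {
  ch <- identity_chain(L = 1000, n_genomes = 2)
  expect_error(propagate_region(region_request("nope", "c1", 1, 10), ch),
               "unknown genome")
  expect_error(propagate_region(region_request("g1", "cX", 1, 10), ch),
               "unknown chromosome")
  expect_error(propagate_region(region_request("g1", "c1", 1, 2000), ch),
               "exceeds")
  expect_error(region_request("g1", "c1", 20, 10), "start <= end")
})

test_that("round-trip mapping contains the original syntenic intersection", {
  fx <- generate_fixture(fixture_spec(n_genomes = 2, chroms_per_genome = 1,
                                      chrom_length = 9000, n_inversions = 1,
                                      n_syn_breaks = 4, seed = 13))
  cmp <- list(blocks = fx$blocks[[1]])
  syn <- fx$blocks[[1]][fx$blocks[[1]]$btype == "SYN", ]
  for (s in c(500, 2500, 6000)) {
    reg <- list(chrom = "chr1", start = s, end = s + 800)
    fwdr <- map_region_step(reg, cmp, "ref2qry")
    backr <- map_region_step(fwdr, cmp, "qry2ref")
    covered <- syn[syn$ref_start <= reg$end & syn$ref_end >= reg$start, ]
    lo <- max(reg$start, min(covered$ref_start))
    hi <- min(reg$end, max(covered$ref_end))
    expect_lte(backr$start, lo)
    expect_gte(backr$end, hi)
  }
})

test_that("zoom selection ignores rearrangement blocks entirely", {
  fx <- generate_fixture(fixture_spec(n_genomes = 3, chroms_per_genome = 2,
                                      chrom_length = 50000, n_inversions = 2,
                                      n_translocations = 1,
                                      n_duplications = 1, seed = 21))
  ch <- fixture_chain(fx)
  req <- region_request("genome1", "chr1", 5000, 15000)
  sel_full <- propagate_region(req, ch)
  # strip all SR blocks and propagate again
  stripped <- lapply(ch$comparisons, function(cmp) {
    pairwise_comparison(cmp$ref_genome, cmp$qry_genome,
                        cmp$blocks[cmp$blocks$btype == "SYN", ])
  })
  ch_syn <- build_chain(unname(ch$genomes), stripped)
  sel_syn <- propagate_region(req, ch_syn)
  expect_equal(as.data.frame(sel_full), as.data.frame(sel_syn))
})

test_that("clip retains exactly the blocks overlapping both windows", {
  ch <- identity_chain(L = 1000, n_genomes = 2)
  blocks <- dplyr::bind_rows(
    mk_block("c1", 1, 1000, "c1", 1, 1000, "SYN", "back"),
    mk_block("c1", 100, 200, "c1", 100, 200, "INV", "inside"),
    mk_block("c1", 150, 250, "c1", 800, 900, "DUP", "qry_out"),
    mk_block("c1", 700, 800, "c1", 700, 800, "INV", "outside"))
  ch$comparisons[[1]] <- pairwise_comparison("g1", "g2", blocks)
  sel <- propagate_region(region_request("g1", "c1", 50, 300), ch)
  clip <- suppressMessages(clip_to_selection(ch, selection = sel))
  got <- clip$chain$comparisons[[1]]$blocks
  expect_setequal(got$source_id, c("back", "inside"))
  # clipping truncates to the window
  expect_equal(got$ref_start[got$source_id == "back"], 50)
  expect_equal(got$ref_end[got$source_id == "back"], 300)
  # fully-inside blocks are untouched
  expect_equal(got$ref_start[got$source_id == "inside"], 100)
})

test_that("clip matches a brute-force double-overlap oracle on random blocks", {
  set.seed(99)
  L <- 10000
  ch <- identity_chain(L = L, n_genomes = 2)
  rs <- sample(L - 100, 200)
  qs <- sample(L - 100, 200)
  blocks <- mk_block("c1", rs, rs + sample(100, 200, TRUE),
                     "c1", qs, qs + sample(100, 200, TRUE),
                     btype = sample(c("SYN", "INV", "TRANS", "DUP"), 200, TRUE),
                     source_id = paste0("b", 1:200))
  blocks$ref_end <- pmin(blocks$ref_end, L)
  blocks$qry_end <- pmin(blocks$qry_end, L)
  ch$comparisons[[1]] <- pairwise_comparison("g1", "g2", blocks)
  sel <- tibble::tibble(genome = c("g1", "g2"), chrom = "c1",
                        start = c(2000, 3000), end = c(6000, 7000))
  class(sel) <- c("sr_zoom", class(sel))
  clip <- suppressMessages(clip_to_selection(ch, selection = sel))
  got <- sort(clip$chain$comparisons[[1]]$blocks$source_id)
  want <- sort(blocks$source_id[
    blocks$ref_start <= 6000 & blocks$ref_end >= 2000 &
      blocks$qry_start <= 7000 & blocks$qry_end >= 3000])
  expect_identical(got, want)
  # monotone shrinkage and idempotence
  expect_lte(length(got), nrow(blocks))
  clip2 <- suppressMessages(clip_to_selection(clip$chain, selection = sel))
  expect_identical(clip2$chain$comparisons[[1]]$blocks,
                   clip$chain$comparisons[[1]]$blocks)
})

test_that("markers and tracks are filtered and re-binned by the selection", {
  ch <- identity_chain(L = 10000, n_genomes = 2)
  sel <- propagate_region(region_request("g1", "c1", 2001, 6000), ch)
  markers <- parse_markers(
    write_tsv_lines(c("c1\t2999\t3000\tg1\ttt:in",
                      "c1\t8999\t9000\tg1\ttt:out"), ext = ".bed"),
    c("g1", "g2"))
  bed <- write_tsv_lines(c("c1\t2099\t2101", "c1\t2999\t3001",
                           "c1\t8000\t8002"), ext = ".bed")
  clip <- suppressMessages(clip_to_selection(
    ch, markers = markers, tracks = list(track_spec(bed, bin_size = 1000)),
    selection = sel))
  expect_equal(clip$markers$label, "in")
  tr <- clip$tracks[[1]]
  expect_equal(nrow(tr), 4)   # ceiling(4000 / 1000) bins over the window
  expect_equal(tr$bin_start[1], 2001)
  expect_equal(sum(tr$value), 2)  # the 8 kb feature is outside the window
})
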