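test_that("chromosome lengths come out of FASTA files, wrapped or gzipped", {
  fa <- write_tsv_lines(c(">c1", "ACGTACGTAC"), ext = ".fa")
  expect_equal(read_chromosome_lengths(fa),
               tibble::tibble(name = "c1", length = 10))

  # wrapped records: length is the count of sequence characters per record
  fa2 <- write_tsv_lines(c(">a desc ignored", "ACGT", "ACG", ">b", "TTT"),
                         ext = ".fasta")
  expect_equal(read_chromosome_lengths(fa2),
               tibble::tibble(name = c("a", "b"), length = c(7, 3)))

  gz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "w")
  writeLines(c(">a desc ignored", "ACGT", "ACG", ">b", "TTT"), con)
  close(con)
  expect_equal(read_chromosome_lengths(gz),
               tibble::tibble(name = c("a", "b"), length = c(7, 3)))
})

test_that("chromosome lengths come out of two-column tables, with hard errors", {
  tsv <- write_tsv_lines(c("c1\t1000", "c2\t500"))
  expect_equal(read_chromosome_lengths(tsv),
               tibble::tibble(name = c("c1", "c2"), length = c(1000, 500)))

  dup <- write_tsv_lines(c("c1\t1000", "c1\t500"))
  expect_error(read_chromosome_lengths(dup), "duplicate chromosome name.*c1")

  bad <- write_tsv_lines(c("c1\t1000", "c2\tforty"))
  expect_error(read_chromosome_lengths(bad), "line 2.*non-integer")

  dupfa <- write_tsv_lines(c(">c1", "AAAA", ">c1", "TT"), ext = ".fa")
  expect_error(read_chromosome_lengths(dupfa), "duplicate chromosome name.*c1")
})

test_that("SyRI parsing keeps structural parents and drops local records", {
  path <- write_tsv_lines(c(
    "c1\t1\t1000\t-\t-\tc1\t1\t1000\tSYN1\t-\tSYN\t-",
    "c1\t10\t10\tA\tT\tc1\t10\t10\tSNP1\tSYN1\tSNP\t-",
    "c1\t1\t1000\t-\t-\tc1\t1\t1000\tSYNAL1\tSYN1\tSYNAL\t-",
    "c1\t2000\t3000\t-\t-\tc1\t3000\t2000\tINV1\t-\tINV\t-",
    "c1\t5000\t5100\t-\t-\t-\t-\t-\tNOTAL1\t-\tNOTAL\t-"
  ))
  b <- parse_syri_tsv(path)
  expect_equal(b$btype, c("SYN", "INV", "NOTAL"))
  expect_equal(b$ref_start, c(1, 2000, 5000))
  # reversed query interval is normalized and flagged
  expect_equal(b$qry_start[b$btype == "INV"], 2000)
  expect_equal(b$qry_end[b$btype == "INV"], 3000)
  expect_true(b$inverted[b$btype == "INV"])
  # NOTAL keeps NA on its missing side
  expect_true(is.na(b$qry_chrom[b$btype == "NOTAL"]))
})

test_that("SyRI parsing counts and hard errors match the dialect", {
  rows <- c(
    sprintf("c1\t%d\t%d\t-\t-\tc1\t%d\t%d\tSYN%d\t-\tSYN\t-",
            c(1, 2001, 5001), c(2000, 5000, 9000),
            c(1, 2001, 5001), c(2000, 5000, 9000), 1:3),
    "c1\t9001\t9500\t-\t-\tc1\t9500\t9001\tINV1\t-\tINV\t-",
    sprintf("c1\t%d\t%d\tA\tT\tc1\t%d\t%d\tSNP%d\tSYN1\tSNP\t-",
            1:500, 1:500, 1:500, 1:500, 1:500)
  )
  b <- parse_syri_tsv(write_tsv_lines(rows))
  expect_equal(nrow(b), 4)

  short <- write_tsv_lines("c1\t1\t1000\tSYN")
  expect_error(parse_syri_tsv(short), "line 1.*12")

  nonnum <- write_tsv_lines("c1\tone\t1000\t-\t-\tc1\t1\t1000\tSYN1\t-\tSYN\t-")
  expect_error(parse_syri_tsv(nonnum), "non-numeric")
})

test_that("BEDPE coordinates shift to 1-based inclusive and types normalize", {
  path <- write_tsv_lines(c(
    "c1\t0\t100\tc1\t0\t100\tSYN",
    "c1\t99\t100\tc2\t0\t1\tTRANS",
    "c1\t200\t300\tc1\t200\t300\tinv",
    "c1\t400\t500\tc1\t600\t700\tDup\tid5",
    "c1\t800\t900\tc1\t800\t900\tsyn"
  ), ext = ".bedpe")
  b <- parse_bedpe(path)
  expect_equal(nrow(b), 5)
  expect_equal(b$ref_start[1], 1)
  expect_equal(b$ref_end[1], 100)
  # single-base intervals
  expect_equal(unlist(b[2, c("ref_start", "ref_end", "qry_start", "qry_end")],
                      use.names = FALSE), c(100, 100, 1, 1))
  expect_equal(b$btype, c("SYN", "TRANS", "INV", "DUP", "SYN"))
  expect_equal(b$source_id[4], "id5")
})

test_that("BEDPE hard errors name the line and the allowed tokens", {
  bad_type <- write_tsv_lines("c1\t0\t100\tc1\t0\t100\tWEIRD", ext = ".bedpe")
  expect_error(parse_bedpe(bad_type), "unknown annotation type.*SYN")
  degen <- write_tsv_lines(c("c1\t0\t100\tc1\t0\t100\tSYN",
                             "c1\t100\t100\tc1\t0\t100\tSYN"), ext = ".bedpe")
  expect_error(parse_bedpe(degen), "line 2")
})

test_that("markers parse BED with genome column and display attributes", {
  path <- write_tsv_lines(c(
    "c1\t999\t1000\tgA\ttt:Inversion",
    "c1\t5\t10\tgA",
    "c2\t0\t1\tgB\tmc:black;ms:8"
  ), ext = ".bed")
  m <- parse_markers(path, c("gA", "gB"))
  expect_equal(m$start, c(1000, 6, 1))
  expect_equal(m$end, c(1000, 10, 1))
  expect_equal(m$label, c("Inversion", "", ""))
  # defaults fill the absent keys
  expect_equal(m$mc, c("black", "black", "black"))
  expect_equal(m$ms, c(3, 3, 8))
  expect_equal(m$mt, rep("v", 3))

  expect_warning(
    parse_markers(write_tsv_lines("c1\t0\t1\tgA\tzz:1;ms:5", ext = ".bed"),
                  "gA"),
    "unknown attribute key 'zz'")
  expect_error(
    parse_markers(write_tsv_lines("c1\t0\t1\tnope", ext = ".bed"), "gA"),
    "line 1.*not configured")
})

test_that("density tracks count midpoints per bin and conserve totals", {
  chroms <- tibble::tibble(name = "c1", length = 200)
  bed <- write_tsv_lines(c("c1\t10\t20", "c1\t30\t40", "c1\t50\t60"),
                         ext = ".bed")
  tr <- load_track_values(track_spec(bed, bin_size = 100), chroms)
  expect_equal(tr$value, c(3, 0))

  # conservation: total count is invariant under binning
  set.seed(42)
  pos <- sort(sample(1e6 - 100, 10))
  big <- write_tsv_lines(paste("chrZ", pos, pos + 50, sep = "\t"),
                         ext = ".bed")
  tr2 <- load_track_values(track_spec(big, bin_size = 1e5),
                           tibble::tibble(name = "chrZ", length = 1e6))
  expect_equal(nrow(tr2), 10)
  expect_equal(sum(tr2$value), 10)
})

test_that("bedGraph tracks average values weighted by overlap", {
  chroms <- tibble::tibble(name = "c1", length = 200)
  bg <- write_tsv_lines("c1\t0\t100\t5.0", ext = ".bedgraph")
  tr <- load_track_values(track_spec(bg, bin_size = 100), chroms)
  expect_equal(tr$value, c(5, 0))

  # two intervals overlapping one bin: weighted mean by overlap length
  bg2 <- write_tsv_lines(c("c1\t0\t50\t2.0", "c1\t50\t100\t6.0"),
                         ext = ".bedgraph")
  tr2 <- load_track_values(track_spec(bg2, bin_size = 100), chroms)
  expect_equal(tr2$value[1], (2 * 50 + 6 * 50) / 100)

  expect_warning(
    load_track_values(track_spec(write_tsv_lines("cX\t0\t10\t1.0",
                                                 ext = ".bedgraph")),
                      chroms),
    "absent from the coordinate genome")
})

test_that("small-variant filtering removes exactly SNP/INS/DEL rows", {
  syn <- sprintf("c1\t%d\t%d\t-\t-\tc1\t%d\t%d\tSYN%d\t-\tSYN\t-",
                 1:4, 11:14, 1:4, 11:14, 1:4)
  snp <- sprintf("c1\t%d\t%d\tA\tT\tc1\t%d\t%d\tV%d\tSYN1\t%s\t-",
                 1:6, 1:6, 1:6, 1:6, 1:6,
                 rep(c("SNP", "INS", "DEL"), 2))
  mixed <- write_tsv_lines(sample(c(syn, snp)))
  out <- tempfile()
  expect_equal(filter_small_variants(mixed, out), 6, ignore_attr = TRUE)
  expect_equal(sum(lengths(strsplit(readLines(out), "\t")) == 12), 4)

  clean <- write_tsv_lines(syn)
  out2 <- tempfile()
  expect_equal(filter_small_variants(clean, out2), 0, ignore_attr = TRUE)
  expect_identical(readLines(out2), readLines(clean))

  # structural parsing is invariant under the filter
  expect_identical(parse_syri_tsv(out), parse_syri_tsv(mixed))
})

test_that("every parsed block satisfies the type invariants", {
  fx <- generate_fixture(fixture_spec(seed = 11, rename_chromosomes = TRUE,
                                      n_small_variants = 50))
  for (p in 1:2) {
    for (b in list(parse_syri_tsv(fx$files[[paste0("syri_", p)]]),
                   parse_bedpe(fx$files[[paste0("bedpe_", p)]]))) {
      expect_true(all(b$btype %in% c("SYN", "INV", "TRANS", "INVTR",
                                     "DUP", "INVDP", "NOTAL")))
      expect_true(all(b$ref_start <= b$ref_end, na.rm = TRUE))
      expect_true(all(b$qry_start <= b$qry_end, na.rm = TRUE))
    }
  }
})
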