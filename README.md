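# srviz

Ribbon-plot visualization of structural similarities and rearrangements
between multiple genome assemblies of a species.

Chromosome-level, haplotype-resolved assemblies let us compare many genomes
of one species directly. Within a species most of each chromosome is
covered by **syntenic regions** — stretches conserved in content, order and
orientation — and everything outside that syntenic backbone is a
**structural rearrangement (SR)**: an inversion, a duplication, or a
translocation (intra- and inter-chromosomal relocations are both called
translocations here). srviz is for researchers who already have pairwise
genome comparisons (e.g. from a whole-genome aligner plus an SR classifier)
and want publication-ready, reproducible figures of those relationships
across an ordered set of genomes — plus the ability to zoom in on any
region of any genome.

## What it computes

Given N genomes in display order and N − 1 pairwise annotation files
(A-vs-B, B-vs-C, ...), srviz:

1. **Validates** that assemblies and structural annotations are mutually
   consistent (chromosome names, interval bounds, chain order), reporting
   all violations at once.
2. **Groups homologous chromosomes** across genomes: for each adjacent
   pair it forms the matrix *M*[r, q] = total syntenic base pairs linking
   reference chromosome r to query chromosome q, takes a greedy
   descending-weight one-to-one assignment, and composes the matchings
   along the chain.
3. **Zooms** (optionally): a region in one genome is propagated outward
   through the chain using only the syntenic backbone. Endpoints are
   mapped by within-block linear interpolation (floor rounding); endpoints
   in inter-block gaps snap to the nearest adjacent block edge; the result
   per genome is the (min, max) of the endpoint images. Content is then
   filtered to blocks overlapping the selected windows on *both* sides.
4. **Lays out** the figure in *stacked* mode (homologous chromosomes in
   vertical columns; best for synteny and intra-chromosomal SRs) or *itx*
   mode (each genome's chromosomes concatenated on one row; inter-
   chromosomal SRs become drawable ribbons).
5. **Renders** deterministic SVG (one polygon per ribbon, one line per
   axis segment, byte-identical across runs), or PDF/PNG. Marker BED files
   and binned feature tracks (gene density, SNP counts, ...) can be drawn
   alongside.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and layouts have `autoplot()`.

## Worked example

The package ships a generator for complete synthetic input bundles with
planted rearrangements, so the example is fully self-contained:

```r
library(srviz)

spec <- fixture_spec(n_genomes = 3, chroms_per_genome = 2,
                     n_inversions = 2, n_translocations = 1,
                     n_duplications = 1, rename_chromosomes = TRUE, seed = 7)
fx <- generate_fixture(spec, "demo_fixture")

genomes <- read_genomes_config(fx$files$genomes_config)
chain <- build_chain(genomes, list(
  pairwise_comparison("genome1", "genome2", parse_syri_tsv(fx$files$syri_1)),
  pairwise_comparison("genome2", "genome3", parse_syri_tsv(fx$files$syri_2))))
chain
#> <sr_chain> 3 genomes: genome1 - genome2 - genome3
#>   genome1 vs genome2: SYN=6 INV=2 TRANS=1 DUP=1
#>   genome2 vs genome3: SYN=6 INV=2 TRANS=1 DUP=1
```

Each comparison parsed to 10 blocks: 6 syntenic tiles plus the 4 planted
events. Homology grouping recovers the chromosome correspondence even
though every genome uses a different naming scheme:

```r
groups <- chain_homology(chain)
groups
#> # A tibble: 6 × 3
#>   order_index genome  chrom
#>         <int> <chr>   <chr>
#> 1           1 genome1 chr1
#> 2           1 genome2 Chr1
#> 3           1 genome3 c1
#> 4           2 genome1 chr2
#> 5           2 genome2 Chr2
#> 6           2 genome3 c2

lay <- render_legend(layout_stacked(chain, groups))
#> stacked mode: skipped 2 inter-chromosomal block(s); use itx mode to draw them
glance(lay)
#> # A tibble: 1 × 6
#>   mode    n_segments n_ribbons n_gaps n_glyphs n_trackbars
#>   <chr>        <int>     <int>  <int>    <int>       <int>
#> 1 stacked          6        18      0        0           0
render_figure(lay, render_config(width = 9, height = 5), "overview.svg")
```

The 18 ribbons are the 20 blocks minus the 2 inter-chromosomal
translocations, which stacked mode skips (use `layout_itx()` to draw
them). Zooming maps a region of the *middle* genome into both neighbours
through the syntenic backbone:

```r
propagate_region(parse_region("genome2:Chr1:200000-400000"), chain)
#> # A tibble: 3 × 4
#>   genome  chrom  start    end
#>   <chr>   <chr>  <dbl>  <dbl>
#> 1 genome1 chr1  200000 400000
#> 2 genome2 Chr1  200000 400000
#> 3 genome3 c1    200000 400000
```

The same pipeline is available from the shell via the installed `srviz`
script (see `exec/srviz`):

```sh
srviz --genomes genomes.tsv --sr pair_1_2.syri.tsv --sr pair_2_3.syri.tsv \
      --reg genome1:chr1:1000-200000 -o zoom.svg
```

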