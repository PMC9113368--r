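---
title: "Methods: multi-genome rearrangement visualization in srviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-genome rearrangement visualization in srviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srviz)
```

## The problem

Chromosome-level, haplotype-resolved assemblies make it possible to compare
many genomes of a single species directly. Within a species, the overall
karyotype is usually conserved: large syntenic regions (the *syntenic
backbone*) cover most of each chromosome, and everything outside the
backbone is, by definition, a structural rearrangement (SR) — an inversion,
a duplication, or a translocation (srviz follows the convention of calling
both intra- and inter-chromosomal relocations translocations). srviz draws
these relationships as ribbon plots across an ordered set of genomes, and
supports zooming on any region of any genome.

The tool deliberately works from *pairwise* comparisons along a chain: to
draw genomes A, B, C in that order it needs A-vs-B and B-vs-C annotations
(for example from whole-genome aligners plus an SR classifier, imported
either in the classifier's native 12-column tab-separated dialect or as
BEDPE). An all-versus-all input model would scale quadratically in the
number of genomes and is rejected by design; the cost is that changing the
display order requires the corresponding pairwise comparisons.

## Data model and validation

The atom of all computation is the alignment block: one interval in the
reference-side genome linked to one interval in the query-side genome with
an annotation type (`SYN`, `INV`, `TRANS`, `INVTR`, `DUP`, `INVDP`,
`NOTAL`). Internally every coordinate is 1-based inclusive; BED-family
inputs (0-based half-open) are converted at the parser boundary and nowhere
else. Query intervals supplied in reversed order (start > end) are
normalized by swapping and flagged as inverted rather than rejected, since
both sign conventions occur in the wild. `NOTAL` (not-aligned) records may
have one empty side; they are retained and drawn as gaps on the axis, never
as ribbons, because silently dropping them would hide assembly problems.

Before any computation, `build_chain()` checks that the genomes and the
structural annotation are mutually consistent: N genomes, exactly N − 1
comparisons in chain order, every chromosome named in a comparison present
in its genome (exact, case-sensitive matching — case-folding would mask
real mismatches between FASTA headers and annotation files), and every
interval within its chromosome's declared length. Validation collects *all*
violations and reports them together, so a user fixes an input file in one
iteration instead of replaying the error-fix loop once per problem.
Comparisons supplied in reversed orientation (B-vs-A in the A→B slot) are
rejected rather than silently flipped; flipping would require swapping
every block's two sides and would mask genuine configuration errors.

## Homology grouping

Chromosomes are grouped across genomes using shared syntenic length. For
one comparison, the weight between reference chromosome r and query
chromosome q is the total `SYN` base pairs (reference side) linking them;
the matching is a greedy descending-weight one-to-one assignment with
lexicographic tie-breaks. Real chromosome-scale synteny matrices are
strongly diagonal-dominant — each chromosome shares almost all of its
syntenic sequence with exactly one partner — and in that regime the greedy
assignment coincides with the optimal one while remaining trivially
auditable. The test suite carries a brute-force maximum-weight matching
oracle (exhaustive search over all permutations of 5×5 matrices) that
documents this agreement on dominant matrices; only the reference side is
weighted because the two sides differ only by indel content.

Per-pair matchings are composed along the chain: each chromosome of
genome 1 seeds one group, extended hop by hop. A break in the chain (a
chromosome matched in pair k but absent from the synteny of pair k + 1)
truncates the group with a warning. Chromosomes left over in later genomes
become singleton groups, so the groups always partition every chromosome of
every genome — unmatched chromosomes are drawn as bare axis lines, not
dropped. Group order follows genome 1's chromosome order, or an explicit
one-name-per-line order file. A chromosome that is mostly inverted relative
to its homolog is *not* auto-flipped; its ribbons will simply appear
crossed, and users who want a flipped display should orient the assembly
accordingly.

## Zooming through the backbone

A zoom request names one region in one genome
(`GENOME:CHROM:START-END`, 1-based inclusive). The homologous interval in
every other genome is found by propagating the region outward through the
chain, one comparison at a time, using **only `SYN` blocks**: rearranged
blocks are passengers, never coordinate anchors, because they are exactly
the regions whose position differs between genomes.

One propagation step works as follows. Among the syntenic blocks whose
source-side interval overlaps the region, the target chromosome is the one
carrying the most overlapping syntenic sequence. Each region endpoint is
then mapped by linear interpolation inside its containing block with floor
rounding; an endpoint falling between blocks snaps to the nearest edge of
the adjacent block's counterpart. The mapped interval is the (min, max) of
the two endpoint images — which also handles locally inverted block order —
clipped to the target chromosome. Floor rounding was chosen because it
makes the endpoint rule *exactly* equal to a definitional per-base oracle
(build the base-to-base table from the blocks, map every base, take the
image extremes), so the geometry is testable with no tolerance at all. A
region with no overlapping syntenic block is a hard error naming the genome
reached and the dead region — this includes a request that falls entirely
inside a not-aligned gap, where no homologous coordinates exist.

Each genome receives a single span rather than a multi-interval set even
when internal inversions scramble order, because each genome is drawn as
one contiguous axis segment. After propagation, drawable content is
filtered: a block is kept only when *both* of its intervals overlap the
selected windows of their genomes (a one-sided ribbon would exit the
canvas), kept blocks are coordinate-clipped, markers are kept when they
overlap their genome's window, and tracks are re-binned over the selected
window only.

## Layout

Layout converts the validated chain into device-independent primitives in
figure units (1 unit per megabase horizontally, 1 unit per genome row
vertically; genome 1 on top). Two modes:

* **stacked** — homologous chromosomes form left-aligned vertical columns;
  ribbons are drawn only within a column (intra-group), which is the right
  view for synteny and intra-chromosomal rearrangements.
  Inter-chromosomal blocks cannot be drawn across columns without crossing
  unrelated genomes, so they are skipped with a logged count.
* **itx** — each genome's chromosomes are concatenated on one row in
  homology-group order, separated by a gap of 2% of the longest genome's
  length; every block type becomes a ribbon, including inter-chromosomal
  translocations and duplications. Zoom cannot be combined with itx mode:
  a zoom selection is one window per genome, which contradicts the
  concatenated-axis premise, so the combination is rejected rather than
  guessed at.

Ribbons are straight-sided quadrilaterals; inversion-type ribbons
(`INV`, `INVTR`, `INVDP`) cross. Straight sides keep the geometry exactly
invertible: the tests recover every source block's coordinates from its
ribbon anchors through the segment coordinate maps. Default colours are
grey for synteny, orange for inversions, green for translocations and blue
for duplications (all overridable); marker glyphs and one histogram row per
track (normalized to the track's in-window maximum; an all-zero track stays
flat rather than dividing by zero) sit above genome 1.

## Rendering

SVG is the structured output: exactly one `polygon` element per ribbon, one
`line` per axis segment, one `rect` per gap or histogram bar, one `circle`
per marker, fixed two-decimal coordinates, and no timestamps or creator
metadata — identical inputs give byte-identical files, and the element
census equals the primitive census, so a figure is fully accounted for by
parsing it back. The SVG writer is purpose-built for this censusable,
deterministic contract. PDF and PNG are produced through R's standard
graphics devices for downstream use; their correctness surface is
"exists, non-empty, openable" since binary formats are not diffable.
Nothing in rendering is randomized; colour cycles are fixed sequences.
A vertical-orientation option is implemented as a 90° transform of the
computed layout (one `g transform` group in SVG, a rotated viewport
otherwise) so there is a single layout code path.

## The fixture generator

`generate_fixture()` emits complete synthetic inputs — length tables,
optional FASTAs, one SyRI-dialect TSV *and* one equivalent BEDPE per pair,
a genomes config, markers, a density track — plus the planted truth
(blocks, homology permutation). Chromosomes are tiled by a syntenic
backbone; planted events are placed non-overlapping at seeded-random
positions with sizes uniform in 1–5% of the chromosome (visible at figure
scale, small enough to tile several events). Inversions keep their
coordinates and flip orientation; translocations relocate to another
chromosome when one exists (making `n_translocations` the planted
inter-chromosomal count); duplications copy a region elsewhere on the
homologous chromosome. A per-step `dilation` factor scales all coordinates
between neighbouring genomes to exercise interpolation, and `n_syn_breaks`
fragments the backbone to reach realistic block counts. FASTA sequences are
all-`A` because only lengths matter downstream. Inversions are written to
the TSV with reversed query coordinates on purpose, so parsing always
exercises normalization.

What the generator does **not** emulate: alignment noise, overlapping or
nested rearrangements, unaligned-edge effects, or biologically realistic
rearrangement processes. Passing tests therefore demonstrate the geometry,
bookkeeping and determinism of the pipeline on clean annotations — they do
not validate any upstream aligner or SR caller, and real data can contain
record types and edge cases (e.g. heavily fragmented backbones near
centromeres) that are only partially represented here.

## Numerical and design choices

* Floor rounding in interpolation; `(min, max)` of endpoint images; gap
  endpoints snap to the adjacent block edge (see above for why).
* Greedy homology assignment with lexicographic tie-breaks; deterministic
  for identical inputs.
* Track bins are `ceiling(length / bin_size)` per chromosome with a
  100 kb default bin, a scale that reads well on chromosome-scale figures;
  density tracks count feature midpoints, value tracks average interval
  values weighted by overlap length; empty bins are zero.
* Duplicate marker loci are kept as given — deduplication would hide
  intentional repeated annotations.
* Small-variant filtering (`filter_small_variants()`) removes SNP/INS/DEL
  rows and nothing else; structural parsing is invariant under it, which
  the suite checks against files salted with ten thousand such rows.

## Problem sizes used in the checks

The automated checks run on sizes chosen to exercise every code path while
keeping an exact, enumerable oracle feasible: 50 seeded two-genome fixtures
with 10 kb chromosomes and 100 probe regions each for the per-base zoom
oracle; 50 three-genome, renamed-chromosome fixtures for homology recovery;
50 random 200-block comparisons for the clip filter; and one six-genome run
with five 10 Mb chromosomes per genome and roughly ten thousand blocks per
pair, parsed, validated, grouped, laid out and rendered to SVG in a few
seconds on one core.

## Limitations

Only a path topology of comparisons is supported; genomes cannot be
reordered without supplying the corresponding comparisons. Zoom produces a
single contiguous window per genome. Stacked mode does not draw
inter-chromosomal ribbons. There is no VCF input, no remote inputs, no
interactive output, and no automatic label collision avoidance beyond
simple vertical offsets.
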