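Package: srviz
Title: Visualize Structural Similarities and Rearrangements Between Multiple Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ribbon-plot visualization of synteny and structural
    rearrangements (inversions, translocations, duplications) across an
    ordered set of genome assemblies compared pairwise along a chain
    (A versus B, B versus C, ...). Reads chromosome lengths from FASTA or
    length tables, structural annotations in the SyRI tab-separated dialect
    or in BEDPE, plus optional marker BED files and feature tracks. Groups
    homologous chromosomes across genomes by shared syntenic length,
    supports zooming on any region of any genome by propagating it through
    the syntenic backbone, lays figures out in stacked or itx mode, and
    renders deterministic SVG as well as PDF and PNG. Includes a synthetic
    fixture generator with planted ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    grid,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
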