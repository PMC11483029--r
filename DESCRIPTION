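Package: bpcompete
Title: Branchpoint Competition Analysis for QKI/SF1-Regulated Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream analysis of intron branchpoint competition between
    the splicing repressor QKI and the branchpoint-binding activator SF1.
    Provides intron-centric splicing-repression quantification from
    class-labeled transcript counts (percent unspliced, base-mean filtering,
    per-gene Student's t tests), two-contrast alternative-splicing
    co-regulation quadrant analysis of dPSI tables, strand-aware extraction
    of 3'-splice-site-proximal intron windows with degenerate-motif scanning
    (overlapping matches), bipartite Quaking-response-element calls,
    dual-motif chi-squared enrichment, RNA-affinity-chromatography proteomics
    enrichment (background correction, sign tallies, row Z-scores,
    differential filters), and a seeded synthetic-data generator with known
    ground truth so every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
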