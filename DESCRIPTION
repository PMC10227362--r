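Package: splicebench
Title: Unified Alternative-Splicing Event Format, Simulation and Benchmark Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking alternative-splicing (AS) event detection and
    splice-aware read mapping. Provides a unified tabular AS event format
    (skipped exons, retained introns, alternative splice-site segments,
    alternative first/last exons) with a deterministic TSV serialization,
    gene-model-aware adapters that normalize the three event-reporting
    conventions found in the field (skipped-exon coordinates, flanking-exon
    coordinates, junction coordinates) into that format, a seeded synthetic
    ground-truth generator that simulates gene models, alternative isoforms
    realizing controlled AS event mixes, and spliced reads with known genomic
    placements, and benchmark metrics: fraction of unmapped reads and mapping
    precision against per-read truth, event-level precision/recall with
    deterministic greedy matching, cross-tool intersection counts and
    minimum-support consensus calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    withr,
    rtracklayer,
    GenomicRanges,
    GenomicAlignments,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
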