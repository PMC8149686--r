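Package: methgrid
Title: Bin-Based Whole-Genome Bisulfite Methylome Analysis with
    Transgenerational DMR Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing data on a
    fixed 200-bp bin grid: per-read filtering of bisulfite-conversion
    failures, per-cytosine methylation levels in CG/CHG/CHH contexts,
    rank-percentile clustering of bins by reference CG methylation,
    Fisher-exact differential-methylation calling with coverage and
    effect-size filters, percentile-matched control region sampling,
    intersection-chain tracking of heritable hyper-CG DMRs across
    transgenic generations, gene-body-methylation classification, genomic
    feature annotation with observed/expected enrichment, and strand-aware
    metaplots over genes, transposons and DMRs. Includes a synthetic
    multi-generation methylome simulator with ground-truth ectopic CG gain
    regions for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    withr,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
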