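Package: scaffeval
Title: Evaluation of Long-Range Genome Scaffolding Technologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to evaluate and compare long-range scaffolding
    technologies (optical-map and proximity-ligation style) applied to a
    fragmented genome assembly: continuity and gap statistics including
    genome-size-adjusted N50, join and break lineage tracking between
    assembly versions, synteny-block construction against a reference
    with chromosome-agreement validation of joins, rearrangement
    breakpoint pinpointing, novel-sequence subtraction with
    low-complexity and tandem-repeat filtering, repeat enrichment in gap
    flanks, and a seeded simulator that generates a reference genome, a
    diverged accession carrying a chromosome-arm translocation,
    fragmented base assemblies, and scaffolded derivatives with full
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
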