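Package: phyllodeg
Title: Transcriptional Responses of Plants to Leaf-Colonizing Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plant transcriptional responses to
    phyllosphere bacteria across inoculation densities. Provides qPCR
    relative quantification with reference-gene and mock normalization,
    colony-count (CFU per gram) quantification with detection-limit and
    pseudo-count handling, dose-response regression against log bacterial
    density, fold-change-threshold differential expression (TREAT-style
    composite null) with TMM normalization and an elbow rule for choosing
    the fold-change cutoff, DEG set algebra (UpSet signatures, nestedness,
    specific/shared partitions) and k-means profile clustering, and
    chromatin-state enrichment of gene sets via a minimum-overlap rule and
    the Marascuilo simultaneous-proportions procedure. A synthetic-data
    generator reproduces the statistical structure of all inputs so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    edgeR,
    multcomp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
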