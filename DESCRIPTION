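Package: promrank
Title: Prioritizing Constitutively Highly Expressed Genes and Their
    Promoters Across Transcriptome Dataset Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-aggregation screen for constitutive promoter discovery in
    fungi and other compact genomes. Genes are ranked by expression intensity
    within each of many transcriptome datasets, per-gene rank profiles are
    summarised by order-statistic median (plus minimum and maximum), unstable
    genes are excluded by a maximum-rank filter, and genes with insufficient
    upstream intergenic space (the available promoter region to the next gene
    body) are excluded by a minimum 5'-UTR filter before the top candidates
    are selected. Includes strand-aware upstream-distance computation from
    GFF3 annotation, capped promoter-window extraction to FASTA/BED, a
    subset-resampling stability analysis of the prioritized list, and a
    synthetic-data generator (expression matrices, genome FASTA, GFF3) with
    planted constitutive genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
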