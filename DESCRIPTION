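Package: drnatss
Title: Primary Transcriptome Annotation and Pan-Genome Analysis for Bacterial dRNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls transcription start sites (TSS) from paired TEX-treated and
    untreated differential RNA-seq 5'-end profiles, classifies them by position
    relative to annotated open reading frames (primary, secondary, internal,
    antisense, intergenic), discovers -10/-35 promoter elements by ZOOPS
    expectation-maximization with permutation significance, summarises 5'UTR
    lengths and Shine-Dalgarno (RBS) spacing, detects the replication origin and
    terminus from cumulative GC skew, and classifies multi-genome protein
    families into core, dispensable and unique categories with Markov
    clustering and a neighbour-joining pan-genome tree. A bundled synthetic-data
    generator plants full ground truth (promoters, RBS sites, TSS classes,
    orthologous families) so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
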