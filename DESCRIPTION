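Package: methtiler
Title: Tile-Based Differential Methylation and Locus-Set Depletion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing
    methylomes organised around fixed-width genomic tiles. Reads CpG-level
    methylation call tables, merges symmetric CpG dyads and biological
    replicates, computes coverage-weighted regional methylation over
    genome-wide or SNP-centred 1-kb tiles, calls differentially methylated
    regions by a methylation-difference threshold, tests locus sets for
    depletion of differential methylation against a background SNP catalogue
    by seeded resampling, assigns loci to promoter/exon/intron/intergenic
    annotation classes with precedence and closest-gene resolution, and
    integrates gene-expression log fold-changes with per-annotation
    methylation differences. Includes a seed-deterministic synthetic
    methylome generator with planted hypomethylated blocks so every stage
    is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
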