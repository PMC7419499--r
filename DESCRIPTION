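Package: tailvar
Type: Package
Title: Breed-Specific SNP Discovery and Stringent Filtering for RNA-Seq Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-calling stages of RNA-seq based SNP discovery in two-breed
    designs: a stringent hard-filter cascade with sequence- and
    annotation-context masks (homopolymer runs, microsatellites with flanks,
    splice-junction intronic flanks, bidirectional-transcription regions),
    known-SNP database intersection, common-SNP and breed-specific SNP
    derivation from per-sample genotypes, variant consequence and impact
    annotation, QTL interval colocalization, cohort statistics (Ts/Tv,
    het/hom ratio, windowed SNP density, EIGENSTRAT-normalized genotype PCA),
    and hypergeometric gene-set enrichment with Benjamini-Hochberg FDR.
    Includes a seeded synthetic two-breed cohort generator with a planted
    truth table for end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
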