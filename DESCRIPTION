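Package: crenrich
Title: LD-Block Enrichment and Cross-Species Conservation of Regulatory
    Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether open-chromatin regions (for example
    scATAC-seq peaks) are enriched within linkage-disequilibrium (LD)
    blocks around trait-associated GWAS variants, and for classifying the
    cross-species conservation of regulatory regions from synteny
    projection scores.  LD blocks are built from phased haplotype panels
    by the proxy-SNP r-squared procedure; significance is assessed against
    background region sets matched to the foreground's joint GC-content
    and genomic-annotation distribution by stratified sampling without
    replacement, with empirical permutation p-values.  A synthetic-data
    module generates haplotype panels with block-structured LD, annotated
    genomes, peak sets with planted enrichment, and projection-score
    tables, so that the whole pipeline is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
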