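Package: bulkscan
Title: Bulked Segregant Analysis and Bulked RNA-Seq Candidate Gene Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conjunctive BSA-seq and BSR-seq analysis for mapping a monogenic
    recessive trait in an F2 population: per-bulk SNP-index computation from
    allelic depths, delta(SNP-index) QTL scanning against a depth-conditional
    simulated null 95% confidence band, candidate-region merging, minimal
    variant-effect annotation against gene models, negative-binomial
    differential expression with three-contrast intersection, hypergeometric
    over-representation analysis, and BSA-by-BSR candidate-gene integration.
    Includes a synthetic-data generator emulating an F2 population segregating
    3:1 for a single recessive sterility locus with phenotype-selected extreme
    bulks, so the whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
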