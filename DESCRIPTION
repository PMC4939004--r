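Package: accessTE
Title: Strain Variation in Chromatin Accessibility at Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying cross-strain variation in
    chromatin accessibility and its relationship to transposable elements
    (TEs) in inbred mouse panels.  Covers strain pseudo-genome construction
    from SNP tables, exact k-mer mappability tracks, kernel-density peak
    calling on FAIRE-type fragment data with a replicate-reproducibility
    filter, quantile normalization and a negative-binomial cross-strain
    variability test that classifies accessible sites into variable and
    common sets, TE class/subfamily/age enrichment analyses, SNP-genotype
    association of accessible sites, differential DNA methylation calling
    and its TE enrichment, and PWM motif scanning with GC-matched background
    enrichment at young versus old LINEs.  A synthetic-data module generates
    genomes, TE annotations, strain SNPs, fragment libraries, count matrices
    and methylation tables with known ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
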