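Package: sirenscape
Title: Cross-Tissue 24nt-siRNA Cluster and DNA Methylation Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of RNA-directed DNA methylation
    landscapes across plant tissues and chromatin-remodeler mutants: calling
    24nt-siRNA clusters from aligned small-RNA read placements, building
    replicate-core and cross-tissue master cluster lists, wild-type-anchored
    negative-binomial differential cluster testing with a hypomethylated-CHH-DMR
    rescue rule, bin-based differentially methylated region calling with
    replicate consensus, siren-locus identification by cumulative abundance,
    CLSY-dependency categorisation, and distributional statistics (k-means
    expression classes, coefficient-of-variation comparison, and permutation
    tests of pericentromeric enrichment). Includes a seeded synthetic-data
    generator emulating the tissue-by-genotype study design so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
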