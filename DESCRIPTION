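Package: popgenscan
Title: Two-Population Genome Scans for Selective Sweeps, Copy-Number
    Differentiation, Linkage Disequilibrium and Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative population-genomic analysis of two small diploid
    cohorts from a multi-sample VCF: variant quality filtering and
    region/coding-effect classification, sliding-window nucleotide diversity
    (theta-pi), Watterson's theta, Tajima's D, Weir-Cockerham Fst and log2
    pi-ratio scans with empirical-quantile sweep selection and candidate-gene
    annotation, Vst scans of copy-number matrices, Haploview-style filtered
    r-squared linkage-disequilibrium decay curves, identity-by-state
    neighbor-joining trees and genotype PCA, and hypergeometric term
    enrichment with Benjamini-Hochberg correction. Ships a synthetic-data
    generator (Balding-Nichols two-population model with planted sweeps and
    differentiated copy-number regions, plus a neutral coalescent window
    simulator) so the whole pipeline is testable end-to-end with exported
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    ape,
    phangorn,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
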