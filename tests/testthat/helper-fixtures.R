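extdata <- function(f) {
  p <- system.file("extdata", f, package = "popgenscan")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", f)
  p
}

# the three-gene toy annotation mirrored in inst/extdata/toy_genes.gff3
toy_gene_models <- function() {
  list(
    geneA = gene_model("geneA", "chrT", "+",
                       exons = rbind(c(1001, 1200), c(1501, 1800),
                                     c(1901, 2000)),
                       cds = rbind(c(1101, 1200), c(1501, 1800),
                                   c(1901, 1959))),
    geneB = gene_model("geneB", "chrT", "-",
                       exons = rbind(c(3001, 4000)),
                       cds = rbind(c(3201, 3800))),
    geneC = gene_model("geneC", "chrT", "+",
                       exons = rbind(c(5001, 5200), c(5401, 5600)),
                       cds = rbind(c(5101, 5200), c(5401, 5501))))
}

# deterministic toy chromosome sequence for coding-effect tests
toy_ref_seq <- function(len = 6000, seed = 2024) {
  withr::with_seed(seed,
                   paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = ""))
}

# 20 variants against the toy genes with hand-derived region labels
toy_region_truth <- function() {
  data.frame(
    pos = c(500, 1001, 1100, 1101, 1200, 1201, 1203, 1350, 1500, 1960,
            2000, 2001, 3100, 3500, 3900, 5050, 5150, 5201, 5300, 5550),
    region = c("intergenic", "UTR5", "UTR5", "CDS", "CDS", "splice",
               "intronic", "intronic", "splice", "UTR3", "UTR3",
               "intergenic", "UTR3", "CDS", "UTR5", "UTR5", "CDS",
               "splice", "intronic", "UTR3"),
    stringsAsFactors = FALSE)
}
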