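test_that("gene models validate exon/CDS geometry", {
  expect_error(gene_model("g", "c", "+", rbind(c(10, 50), c(40, 80))),
               "non-overlapping")
  expect_error(gene_model("g", "c", "+", rbind(c(10, 50)),
                          cds = rbind(c(40, 60))), "inside exons")
  expect_error(gene_model("g", "c", "*", rbind(c(10, 50))), "strand")
})

test_that("the GFF3 reader reproduces the hand-built toy models", {
  models <- read_gene_models(extdata("toy_genes.gff3"))
  built <- toy_gene_models()
  expect_setequal(names(models), names(built))
  for (g in names(built)) {
    expect_equal(models[[g]]$exons, built[[g]]$exons)
    expect_equal(models[[g]]$cds, built[[g]]$cds)
    expect_equal(models[[g]]$strand, built[[g]]$strand)
  }
})

test_that("region assignment reproduces the 20 hand-derived labels", {
  truth <- toy_region_truth()
  got <- assign_region(rep("chrT", nrow(truth)), truth$pos,
                       toy_gene_models())
  expect_equal(got$region, truth$region)
  # every variant gets exactly one region (partition property)
  expect_true(all(got$region %in% c("intergenic", "intronic", "UTR5",
                                    "UTR3", "CDS", "splice")))
  expect_true(all(is.na(got$gene_id[got$region == "intergenic"])))
  expect_true(all(!is.na(got$gene_id[got$region != "intergenic"])))
})

test_that("variants on chromosomes without models are intergenic with a warning", {
  expect_warning(got <- assign_region("chrZ", 100, toy_gene_models()),
                 "chrZ")
  expect_equal(got$region, "intergenic")
})

test_that("a variant spanned by two genes is classified against the first by start", {
  models <- list(
    late = gene_model("late", "c", "+", rbind(c(150, 400))),
    early = gene_model("early", "c", "+", rbind(c(100, 300)),
                       cds = rbind(c(120, 290))))
  got <- assign_region("c", 200, models)
  expect_equal(got$gene_id, "early")
  expect_equal(got$n_genes, 2L)
})

test_that("coding effects match brute-force translation for all minus-strand SNPs", {
  # one-codon CDS on the minus strand at positions 11..13
  refseq <- "AAAAAAAAAACATGGGGGGGGG"  # plus strand; minus-strand codon = ATG
  model <- gene_model("g", "c", "-", rbind(c(11, 13)),
                      cds = rbind(c(11, 13)))
  code <- Biostrings::GENETIC_CODE
  for (pos in 11:13) {
    ref <- substr(refseq, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- classify_coding_effect(pos, ref, alt, model, refseq)
      # oracle: substitute on the plus strand, reverse-complement, translate
      mutated <- refseq
      substr(mutated, pos, pos) <- alt
      rc <- function(s) chartr("ACGT", "TGCA",
                               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
      aa_ref <- unname(code[rc(substr(refseq, 11, 13))])
      aa_alt <- unname(code[rc(substr(mutated, 11, 13))])
      want <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "stopgain"
      else if (aa_ref == "*") "stoploss"
      else "nonsynonymous"
      expect_equal(got$effect, want,
                   label = sprintf("pos %d %s>%s: %s", pos, ref, alt,
                                   got$effect))
    }
  }
})

test_that("textbook codon changes classify as expected", {
  # GGA -> GGG synonymous (third position), on the plus strand
  refseq <- paste0(strrep("A", 10), "GGA", strrep("C", 10))
  model <- gene_model("g", "c", "+", rbind(c(11, 13)),
                      cds = rbind(c(11, 13)))
  expect_equal(classify_coding_effect(13, "A", "G", model, refseq)$effect,
               "synonymous")
  # TGG -> TGA stopgain
  refseq2 <- paste0(strrep("A", 10), "TGG", strrep("C", 10))
  expect_equal(classify_coding_effect(13, "G", "A", model, refseq2)$effect,
               "stopgain")
  expect_error(classify_coding_effect(13, "C", "G", model, refseq2),
               "mismatch")
})

test_that("strand symmetry: minus-strand classification equals the mirrored plus-strand one", {
  withr::local_seed(61)
  base <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    cds <- paste(sample(base, 9, replace = TRUE), collapse = "")
    seq_plus <- paste0("AAAA", cds, "TTTT")
    m_plus <- gene_model("g", "c", "+", rbind(c(5, 13)),
                         cds = rbind(c(5, 13)))
    # equivalent minus-strand model carries the reverse complement
    seq_minus <- paste0("AAAA",
                        chartr("ACGT", "TGCA",
                               paste(rev(strsplit(cds, "")[[1]]),
                                     collapse = "")), "TTTT")
    m_minus <- gene_model("g", "c", "-", rbind(c(5, 13)),
                          cds = rbind(c(5, 13)))
    pos <- sample(5:13, 1)
    ref <- substr(seq_plus, pos, pos)
    alt <- sample(setdiff(base, ref), 1)
    mirror_pos <- 13 - (pos - 5)
    comp <- function(x) chartr("ACGT", "TGCA", x)
    e1 <- classify_coding_effect(pos, ref, alt, m_plus, seq_plus)
    e2 <- classify_coding_effect(mirror_pos, comp(ref), comp(alt), m_minus,
                                 seq_minus)
    expect_equal(e1$effect, e2$effect)
  }
})

test_that("effect summaries count categories, ratios and InDel spectra", {
  s <- effect_summary(regions = rep("CDS", 174),
                      effects = rep(c("nonsynonymous", "synonymous"),
                                    c(74, 100)))
  expect_equal(s$nonsyn_syn_ratio, 0.74)
  expect_equal(sum(s$region_counts), 174)
  s0 <- effect_summary(regions = character(0))
  expect_true(is.na(s0$nonsyn_syn_ratio))
  expect_equal(sum(s0$effect_counts), 0)
  lens <- c(rep(1, 50), rep(3, 30), rep(6, 15), rep(40, 5))
  s1 <- effect_summary(rep("intergenic", 100), indel_lengths = lens)
  expect_equal(s1$share_1_6bp, 0.95)
  expect_equal(s1$share_inframe, 0.45)
  expect_equal(sum(s1$indel_hist), 100)
  expect_equal(unname(s1$indel_hist["3"]), 30L)
})

test_that("recovered effect proportions match a planted mix within binomial error", {
  withr::local_seed(62)
  # plant codons and SNPs so ~40% of coding changes are synonymous
  code <- Biostrings::GENETIC_CODE
  n <- 400
  effects <- character(n)
  refseq_codon <- "CTG"  # leucine: 3rd-position changes synonymous
  for (i in seq_len(n)) {
    syn <- runif(1) < 0.4
    refseq <- paste0(strrep("A", 10), refseq_codon, strrep("C", 10))
    model <- gene_model("g", "c", "+", rbind(c(11, 13)),
                        cds = rbind(c(11, 13)))
    if (syn) {
      eff <- classify_coding_effect(13, "G", "A", model, refseq)  # CTG->CTA
    } else {
      eff <- classify_coding_effect(12, "T", "A", model, refseq)  # CTG->CAG
    }
    effects[i] <- eff$effect
  }
  s <- effect_summary(rep("CDS", n), effects)
  prop_syn <- unname(s$effect_counts["synonymous"]) / n
  expect_lt(abs(prop_syn - 0.4), 3 * sqrt(0.4 * 0.6 / n))
})
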