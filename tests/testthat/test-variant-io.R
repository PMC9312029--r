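test_that("the 10-record toy VCF reads with ascending positions and round-trips", {
  res <- read_vcf(extdata("toy10.vcf"), extdata("toy10_pops.tsv"))
  vs <- res$records
  expect_equal(length(vs), 10L)
  for (chr in unique(vs$site$chrom))
    expect_true(!is.unsorted(vs$site$pos[vs$site$chrom == chr],
                             strictly = TRUE))
  expect_equal(sum(vs$site$multiallelic), 1L)
  # matrices: one per chromosome, biallelic only, missing preserved
  expect_named(res$matrices, c("chr1", "chr2"))
  expect_equal(ncol(res$matrices$chr1$G), 5L)  # 6 records, 1 multiallelic
  expect_true(is.na(res$matrices$chr1$G["A2", 4]))  # ./. genotype
  # round-trip
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, out)
  back <- read_vcf(out, extdata("toy10_pops.tsv"))$records
  expect_equal(back$site, vs$site)
  expect_equal(back$gt, vs$gt)
  expect_equal(back$sr, vs$sr)
})

test_that("a sample missing from the population map is a configuration error", {
  expect_error(read_vcf(extdata("toy10.vcf"),
                        c(A1 = "popA", A2 = "popA")),
               "not in pop_map")
  expect_error(read_vcf(extdata("toy10.vcf"),
                        c(A1 = "popA", A2 = "popA", B1 = "popB",
                          ghost = "popB")),
               "not in VCF header")
})

test_that("an empty record set writes a valid header-only VCF", {
  vs <- variant_set(data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               qual = numeric(0), depth = integer(0)),
                    gt = matrix(character(0), 0, 2,
                                dimnames = list(NULL, c("a", "b"))))
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, out)
  back <- read_vcf(out)
  expect_equal(length(back$records), 0L)
  expect_equal(back$records$samples, c("a", "b"))
})

test_that("simulated VCF round-trips to the generator's truth dosage matrix", {
  cfg <- sim_config(seed = 31, n_windows = 20, sites_per_window = 25,
                    sweep_n = 0)
  sim <- simulate_two_pop_vcf(cfg, dir = withr::local_tempdir())
  expect_equal(length(sim$positions), 500L)
  res <- read_vcf(sim$vcf, sim$pop_map)
  gm <- res$matrices[[cfg$chrom]]
  expect_equal(ncol(gm$G), 500L)
  expect_equal(unname(gm$G), unname(sim$dosages))
  expect_equal(gm$positions, sim$positions)
  # writing the parsed records again reproduces the dosages
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(res$records, out)
  gm2 <- read_vcf(out, sim$pop_map)$matrices[[cfg$chrom]]
  expect_equal(gm2$G, gm$G)
})

test_that("the 12-record filter fixture yields exactly the hand-annotated survivors", {
  res <- read_vcf(extdata("filter12.vcf"))
  flt <- filter_variants(res$records, filter_config())
  expect_equal(flt$records$site$pos,
               c(100, 600, 700, 800, 900, 1000, 1100))
  # boundary records rejected for the right reason
  reasons <- setNames(flt$reason, res$records$site$pos)
  expect_equal(unname(reasons["200"]), "qual")       # qual = 20 exactly
  expect_equal(unname(reasons["300"]), "supporting_reads")
  expect_equal(unname(reasons["400"]), "depth")      # depth = 100 exactly
  expect_equal(unname(reasons["500"]), "maf")        # MAF = 0.05 exactly
  expect_equal(unname(reasons["103"]), "spacing")
  expect_equal(unname(flt$counts["survivors"]), 7L)
})

test_that("rejection counts sum to the input size and filtering is idempotent", {
  res <- read_vcf(extdata("filter12.vcf"))
  flt <- filter_variants(res$records)
  expect_equal(sum(flt$counts), length(res$records))
  again <- filter_variants(flt$records)
  expect_equal(again$records$site, flt$records$site)
  expect_equal(unname(again$counts["survivors"]),
               unname(flt$counts["survivors"]))
})

test_that("SNPs exactly min_spacing apart both survive", {
  site <- data.frame(chrom = "c", pos = c(10L, 15L), ref = c("A", "C"),
                     alt = c("G", "T"), qual = c(50, 50),
                     depth = c(50L, 50L))
  gt <- matrix(c("0/1", "0/1", "0/1", "0/1", "0/0", "0/0", "0/0", "0/0"),
               2, 4, dimnames = list(NULL, paste0("s", 1:4)))
  sr <- matrix(20, 2, 4)
  flt <- filter_variants(variant_set(site, gt, sr))
  expect_equal(unname(flt$counts["survivors"]), 2L)
})

test_that("unsorted records are rejected and optional rules warn when columns are absent", {
  site <- data.frame(chrom = "c", pos = c(20L, 10L), ref = c("A", "C"),
                     alt = c("G", "T"), qual = c(50, 50),
                     depth = c(50L, 50L))
  gt <- matrix("0/1", 2, 4, dimnames = list(NULL, paste0("s", 1:4)))
  vs <- variant_set(site, gt, matrix(20, 2, 4))
  expect_error(filter_variants(vs), "sorted")
  vs2 <- vs[order(vs$site$pos)]
  expect_warning(filter_variants(vs2, filter_config(max_copy_number = 1.5)),
                 "max_copy_number")
})
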