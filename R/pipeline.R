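#' End-to-end sweep-scan pipeline on simulated data
#'
#' Runs the full chain: simulate a two-population VCF with planted sweeps,
#' read it back, apply the variant filters, scan windows, select sweep
#' windows for the focal population, merge them into regions, collect
#' candidate genes from the simulated annotation and test term enrichment.
#'
#' @param cfg a [sim_config()].
#' @param dir working directory for the emitted files.
#' @param criteria a [sweep_criteria()]; defaults to the shipped criteria
#'   with the simulation's focal population.
#' @param filter a [filter_config()].
#' @param window_size,window_step scan grid; defaults to the simulation's
#'   non-overlapping window grid so selected windows map one-to-one onto
#'   planted ones.
#' @return List with `sim`, `filtered`, `stats`, `selected` (window table),
#'   `regions`, `candidates`, `enrichment`, `annotation` and `truth`.
#' @export
run_sweep_pipeline <- function(cfg = sim_config(), dir = tempdir(),
                               criteria = NULL,
                               filter = filter_config(),
                               window_size = cfg$window_bp,
                               window_step = cfg$window_bp) {
  sim <- simulate_two_pop_vcf(cfg, dir)
  vcf <- read_vcf(sim$vcf, sim$pop_map)
  flt <- filter_variants(vcf$records, filter)
  gm <- genotype_matrices(flt$records, sim$pop_map)[[cfg$chrom]]
  windows <- make_windows(stats::setNames(sim$chrom_length, cfg$chrom),
                          window_size, window_step)
  stats <- scan_windows(gm, windows)
  if (is.null(criteria)) criteria <- sweep_criteria(cfg$sweep_pop)
  sel <- select_sweep_windows(stats, criteria)
  ann <- simulate_annotation(cfg, dir)
  regions <- merge_and_annotate(sel, ann$genes, criteria$flank_bp)
  cand <- candidate_genes(regions)
  enr <- if (length(cand))
    enrich(cand, ann$terms, background = ann$genes$gene_id) else NULL
  list(sim = sim, filtered = flt, gm = gm, stats = stats, selected = sel,
       regions = regions, candidates = cand, enrichment = enr,
       annotation = ann, truth = sim$truth)
}
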