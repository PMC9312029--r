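#' Simulation configuration
#'
#' Generating parameters of the synthetic two-population study. The defaults
#' emulate the study design this package targets: two small diploid cohorts
#' (5 + 3 individuals), mild genome-wide background differentiation, a small
#' number of planted sweep windows with strongly reduced diversity in the
#' focal population, planted population-differentiated copy-number regions,
#' and toy gene/term annotations with one over-represented term among genes
#' in the planted sweep windows. Planted windows/regions are placed evenly
#' along the chromosome, so the ground truth depends only on the plan, not
#' on the random seed.
#'
#' @param seed base random seed; derived generators use small fixed offsets.
#' @param n_pop named integer vector of diploid cohort sizes (exactly two).
#' @param chrom chromosome name.
#' @param n_windows number of non-overlapping windows simulated.
#' @param window_bp window size in bp.
#' @param sites_per_window SNP sites simulated per window.
#' @param background_fst Balding-Nichols differentiation parameter `F` in
#'   `[0, 1)`.
#' @param sweep_n planted sweep windows (`<= n_windows`).
#' @param sweep_reduction factor (`> 1`) by which focal-population expected
#'   heterozygosity is reduced in sweep windows.
#' @param sweep_pop focal (swept) population label; default the second
#'   (smaller) cohort.
#' @param sweep_extra_rare extra singleton sites added per sweep window
#'   (guarantees segregating sites with an excess of rare variants, hence
#'   negative Tajima's D, in swept windows).
#' @param frac_low_qual,frac_low_support,frac_high_depth fractions of sites
#'   emitted with a failing QUAL, a failing per-sample supporting-read
#'   count, and a failing total depth, respectively.
#' @param cnv_n_regions,cnv_region_bp,cnv_diff_n,cnv_shift,cnv_sd
#'   copy-number plan: region count and length, number of differentiated
#'   regions, between-population mean shift, within-population SD around a
#'   diploid baseline of 2.
#' @param gene_bp,gene_gap_bp gene tiling for the toy annotation.
#' @param n_terms,term_prob,n_planted_terms,enrich_factor term annotation
#'   plan: term count, baseline gene-term probability, number of planted
#'   terms, and the over-representation factor applied to genes inside
#'   planted sweep windows.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_pop = c(popA = 5L, popB = 3L),
                       chrom = "chr1",
                       n_windows = 200L, window_bp = 40000L,
                       sites_per_window = 25L,
                       background_fst = 0.1,
                       sweep_n = 10L, sweep_reduction = 8,
                       sweep_pop = names(n_pop)[2],
                       sweep_extra_rare = 5L,
                       frac_low_qual = 0.02, frac_low_support = 0.02,
                       frac_high_depth = 0.02,
                       cnv_n_regions = 1000L, cnv_region_bp = 5000L,
                       cnv_diff_n = 50L, cnv_shift = 2, cnv_sd = 0.2,
                       gene_bp = 3000L, gene_gap_bp = 1000L,
                       n_terms = 40L, term_prob = 0.05,
                       n_planted_terms = 1L, enrich_factor = 5) {
  stopifnot(length(n_pop) == 2L, all(n_pop >= 1L),
            background_fst >= 0, background_fst < 1,
            sweep_reduction > 1, sweep_n >= 0)
  if (is.null(names(n_pop))) names(n_pop) <- c("popA", "popB")
  if (sweep_n > n_windows)
    stop("infeasible plan: more sweep windows (", sweep_n,
         ") than windows (", n_windows, ")")
  if (cnv_diff_n > cnv_n_regions)
    stop("infeasible plan: more differentiated regions than regions")
  structure(list(seed = as.integer(seed), n_pop = n_pop, chrom = chrom,
                 n_windows = as.integer(n_windows),
                 window_bp = as.integer(window_bp),
                 sites_per_window = as.integer(sites_per_window),
                 background_fst = background_fst,
                 sweep_n = as.integer(sweep_n),
                 sweep_reduction = sweep_reduction, sweep_pop = sweep_pop,
                 sweep_extra_rare = as.integer(sweep_extra_rare),
                 frac_low_qual = frac_low_qual,
                 frac_low_support = frac_low_support,
                 frac_high_depth = frac_high_depth,
                 cnv_n_regions = as.integer(cnv_n_regions),
                 cnv_region_bp = as.integer(cnv_region_bp),
                 cnv_diff_n = as.integer(cnv_diff_n),
                 cnv_shift = cnv_shift, cnv_sd = cnv_sd,
                 gene_bp = as.integer(gene_bp),
                 gene_gap_bp = as.integer(gene_gap_bp),
                 n_terms = as.integer(n_terms), term_prob = term_prob,
                 n_planted_terms = as.integer(n_planted_terms),
                 enrich_factor = enrich_factor),
            class = "sim_config")
}

#' Planted sweep-window indices (1-based, deterministic)
#'
#' Evenly spaced over the simulated windows; a function of the plan only.
#'
#' @param cfg a [sim_config()].
#' @return Integer vector of window indices.
#' @export
planted_sweep_windows <- function(cfg) {
  if (cfg$sweep_n == 0L) return(integer(0))
  unique(floor(seq_len(cfg$sweep_n) * cfg$n_windows / (cfg$sweep_n + 1)))
}

planted_cnv_regions <- function(cfg) {
  if (cfg$cnv_diff_n == 0L) return(integer(0))
  unique(floor(seq_len(cfg$cnv_diff_n) * cfg$cnv_n_regions /
                 (cfg$cnv_diff_n + 1)))
}

#' Simulate one neutral coalescent window
#'
#' Standard neutral coalescent without recombination: exponential
#' coalescence times with rate `choose(k, 2)`, Poisson mutations on branches
#' at rate `theta / 2` per unit branch length, infinite-sites placement.
#'
#' @param n number of haplotypes (`>= 2`).
#' @param theta scaled mutation rate of the window (`> 0`).
#' @param seed optional seed.
#' @return List with `haplotypes` (0/1 matrix, `n` x `S`) and `positions`
#'   (sorted uniforms on (0, 1), one per segregating site).
#' @export
simulate_neutral_window <- function(n, theta, seed = NULL) {
  stopifnot(n >= 2, theta > 0)
  if (!is.null(seed)) set.seed(seed)
  active <- as.list(seq_len(n))
  birth <- rep(0, n)
  segs_sets <- vector("list", 2 * (n - 1))
  segs_len <- numeric(2 * (n - 1))
  nseg <- 0L
  t <- 0
  k <- n
  while (k > 1) {
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pair <- sort(sample.int(k, 2))
    for (idx in pair) {
      nseg <- nseg + 1L
      segs_sets[[nseg]] <- active[[idx]]
      segs_len[nseg] <- t - birth[idx]
    }
    active[[pair[1]]] <- c(active[[pair[1]]], active[[pair[2]]])
    birth[pair[1]] <- t
    active[[pair[2]]] <- NULL
    birth <- birth[-pair[2]]
    k <- k - 1L
  }
  muts <- stats::rpois(nseg, theta / 2 * segs_len[seq_len(nseg)])
  S <- sum(muts)
  M <- matrix(0L, n, S)
  col <- 0L
  for (i in seq_len(nseg)) {
    if (muts[i] > 0) for (j in seq_len(muts[i])) {
      col <- col + 1L
      M[segs_sets[[i]], col] <- 1L
    }
  }
  pos <- sort(stats::runif(S))
  list(haplotypes = M, positions = pos)
}

# expected heterozygosity of a background site: ancestral p ~ U(0.05, 0.95),
# population frequency Balding-Nichols with parameter F
background_het <- function(F) {
  a <- 0.05; b <- 0.95
  e_pq <- (a + b) / 2 - ((b - a)^2 / 12 + ((a + b) / 2)^2)
  2 * e_pq * (1 - F)
}

# near-fixation width eps such that q ~ U(0, eps) has expected 2q(1-q)
# equal to the background heterozygosity divided by the reduction factor
sweep_eps <- function(F, reduction) {
  target <- background_het(F) / reduction
  stats::uniroot(function(e) e - 2 / 3 * e^2 - target, c(1e-9, 0.5))$root
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Simulate a two-population VCF with planted sweeps
#'
#' Background sites follow the Balding-Nichols model: ancestral frequency
#' `p ~ U(0.05, 0.95)`, population frequencies
#' `~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, diploid genotypes
#' `Binomial(2, p_pop)`. In planted sweep windows the focal population's
#' frequency is pushed to within `eps` of fixation, with `eps` calibrated so
#' the focal expected heterozygosity drops by `sweep_reduction`, and a few
#' extra focal singletons are added (excess rare variants). QUAL, INFO/DP
#' and per-sample DP are drawn so that small configured fractions of records
#' fail each filter rule. Identical seed and config give byte-identical
#' files.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return List with `vcf`, `pop_map` (file paths), `truth` (planted window
#'   coordinates and parameters), `dosages` (samples x sites truth matrix),
#'   `positions`, `pops` and `chrom_length`.
#' @export
simulate_two_pop_vcf <- function(cfg = sim_config(), dir = tempdir()) {
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- names(cfg$n_pop)
  samples <- unlist(lapply(seq_along(labs), function(i)
    sprintf("%s_%02d", labs[i], seq_len(cfg$n_pop[i]))))
  pops <- stats::setNames(rep(labs, cfg$n_pop), samples)
  focal <- cfg$sweep_pop
  if (!focal %in% labs) stop("sweep_pop must be one of ", paste(labs, collapse = ", "))
  sweep_idx <- planted_sweep_windows(cfg)
  W <- cfg$window_bp
  F <- cfg$background_fst
  eps <- if (cfg$sweep_n > 0) sweep_eps(F, cfg$sweep_reduction) else NA_real_
  pos_list <- list(); meta <- list()
  for (w in seq_len(cfg$n_windows)) {
    n_extra <- if (w %in% sweep_idx) cfg$sweep_extra_rare else 0L
    k <- cfg$sites_per_window + n_extra
    p <- sort(sample.int(W - 1L, k)) + (w - 1L) * W  # 1-based positions
    pos_list[[w]] <- p
    meta[[w]] <- rep(c("bg", "rare"), c(cfg$sites_per_window, n_extra))
    if (n_extra > 0) {  # scatter the rare sites among the window's sites
      meta[[w]] <- sample(meta[[w]])
    }
    if (w %in% sweep_idx)
      meta[[w]][meta[[w]] == "bg"] <- "sweep"
  }
  positions <- unlist(pos_list)
  kind <- unlist(meta)
  n_sites <- length(positions)
  n_ind <- sum(cfg$n_pop)
  G <- matrix(NA_integer_, n_ind, n_sites,
              dimnames = list(samples, NULL))
  draw_pop_freq <- function(p) {
    if (F == 0) return(p)
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  p_anc <- stats::runif(n_sites, 0.05, 0.95)
  for (lab in labs) {
    rows <- which(pops == lab)
    p_pop <- draw_pop_freq(p_anc)
    if (lab == focal && cfg$sweep_n > 0) {
      # the swept haplotype fixes one allele; which one is a draw with
      # probability equal to its ancestral frequency, so fixation elevates
      # differentiation whatever the locally common allele was
      sw <- which(kind == "sweep")
      u <- stats::runif(length(sw), 0, eps)
      side <- stats::rbinom(length(sw), 1L, p_anc[sw])
      p_pop[sw] <- ifelse(side == 1L, 1 - u, u)
    }
    for (r in rows) G[r, ] <- stats::rbinom(n_sites, 2L, p_pop)
    rare <- which(kind == "rare")
    if (length(rare)) {
      if (lab == focal) {
        G[rows, rare] <- 0L
        carrier <- rows[1 + (seq_along(rare) %% length(rows))]
        G[cbind(carrier, rare)] <- 1L
      } else {
        G[rows, rare] <- 0L
      }
    }
  }
  # record fields: QUAL, total depth, per-sample depth, with planted failures
  qual <- round(stats::runif(n_sites, 30, 60), 1)
  fail_q <- stats::runif(n_sites) < cfg$frac_low_qual
  qual[fail_q] <- round(stats::runif(sum(fail_q), 5, 20), 1)
  depth <- stats::rpois(n_sites, 60)
  fail_d <- stats::runif(n_sites) < cfg$frac_high_depth
  depth[fail_d] <- 100L + stats::rpois(sum(fail_d), 50)
  sr <- matrix(stats::rpois(n_ind * n_sites, 23) + 5L, n_sites, n_ind)
  fail_s <- stats::runif(n_sites) < cfg$frac_low_support
  if (any(fail_s))
    sr[cbind(which(fail_s),
             sample.int(n_ind, sum(fail_s), replace = TRUE))] <-
      sample(0:4, sum(fail_s), replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  site <- data.frame(chrom = cfg$chrom, pos = positions, ref = ref,
                     alt = unname(alt), qual = qual, depth = depth,
                     stringsAsFactors = FALSE)
  gt <- apply(G, 1L, dosage_to_gt)  # sites x samples
  gt[gt == "./."] <- NA_character_
  colnames(gt) <- samples
  vs <- variant_set(site, gt, sr, samples = samples)
  chrom_length <- cfg$n_windows * W
  vcf_path <- file.path(dir, "simulated.vcf")
  write_vcf(vs, vcf_path,
            contigs = stats::setNames(chrom_length, cfg$chrom))
  pop_path <- file.path(dir, "pop_map.tsv")
  utils::write.table(data.frame(sample = samples, population = unname(pops)),
                     pop_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- list(
    sweep_windows = data.frame(chrom = rep(cfg$chrom, length(sweep_idx)),
                               start = (sweep_idx - 1L) * W,
                               end = sweep_idx * W,
                               index = sweep_idx),
    eps = eps, config = cfg, site_kind = kind)
  list(vcf = vcf_path, pop_map = pop_path, truth = truth,
       dosages = G, positions = positions, pops = pops,
       chrom_length = chrom_length, records = vs)
}

#' Simulate a copy-number matrix with differentiated regions
#'
#' Null regions draw every sample's copy number from `Normal(2, cnv_sd)`;
#' planted regions separate the two population means by `cnv_shift`.
#'
#' @param cfg a [sim_config()].
#' @param path optional TSV output path (written when non-`NULL`).
#' @return List with `cnm` (a [cn_matrix()]), `truth` (planted region
#'   indices and coordinates) and `path`.
#' @export
simulate_cnv <- function(cfg = sim_config(), path = NULL) {
  set.seed(cfg$seed + 1L)
  labs <- names(cfg$n_pop)
  samples <- unlist(lapply(seq_along(labs), function(i)
    sprintf("%s_%02d", labs[i], seq_len(cfg$n_pop[i]))))
  pops <- stats::setNames(rep(labs, cfg$n_pop), samples)
  n <- cfg$cnv_n_regions
  span <- 2L * cfg$cnv_region_bp
  regions <- data.frame(chrom = cfg$chrom,
                        start = (seq_len(n) - 1L) * span,
                        end = (seq_len(n) - 1L) * span + cfg$cnv_region_bp)
  diff_idx <- planted_cnv_regions(cfg)
  mu <- matrix(2, n, length(samples))
  if (length(diff_idx))
    mu[diff_idx, pops[samples] == labs[2]] <- 2 + cfg$cnv_shift
  CN <- matrix(pmax(0, stats::rnorm(n * length(samples), mu, cfg$cnv_sd)),
               n, length(samples), dimnames = list(NULL, samples))
  cnm <- cn_matrix(regions, CN, pops)
  if (!is.null(path)) {
    tab <- cbind(regions, as.data.frame(CN, check.names = FALSE))
    utils::write.table(format(tab, trim = TRUE, scientific = FALSE,
                              digits = 15),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(cnm = cnm,
       truth = list(diff_regions = regions[diff_idx, , drop = FALSE],
                    index = diff_idx, config = cfg),
       path = path)
}

#' Simulate gene spans and term annotations
#'
#' Genes are tiled with gaps along the simulated chromosome; each gene gets
#' each term with the baseline probability, except that planted terms are
#' over-represented (by `enrich_factor`) among genes overlapping planted
#' sweep windows.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when non-`NULL`, writes
#'   `genes.bed` (0-based half-open) and `terms.tsv` (gene, term).
#' @return List with `genes` (data.frame `chrom`, `start`, `end`,
#'   `gene_id`), `terms` (data.frame `gene`, `term`), `truth` (planted term
#'   ids and sweep-gene ids) and file paths when written.
#' @export
simulate_annotation <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed + 2L)
  chrom_length <- cfg$n_windows * cfg$window_bp
  pitch <- cfg$gene_bp + cfg$gene_gap_bp
  starts <- seq(0L, chrom_length - cfg$gene_bp, by = pitch)
  genes <- data.frame(chrom = cfg$chrom, start = starts,
                      end = starts + cfg$gene_bp,
                      gene_id = sprintf("gene%04d", seq_along(starts)),
                      stringsAsFactors = FALSE)
  sweep_idx <- planted_sweep_windows(cfg)
  sw_start <- (sweep_idx - 1L) * cfg$window_bp
  sw_end <- sweep_idx * cfg$window_bp
  in_sweep <- vapply(seq_len(nrow(genes)), function(i)
    any(genes$start[i] < sw_end & genes$end[i] > sw_start), logical(1))
  term_ids <- sprintf("term%02d", seq_len(cfg$n_terms))
  planted_terms <- utils::head(term_ids, cfg$n_planted_terms)
  rows <- list()
  for (tm in term_ids) {
    pr <- rep(cfg$term_prob, nrow(genes))
    if (tm %in% planted_terms)
      pr[in_sweep] <- pmin(1, cfg$term_prob * cfg$enrich_factor)
    keep <- stats::runif(nrow(genes)) < pr
    if (any(keep))
      rows[[tm]] <- data.frame(gene = genes$gene_id[keep], term = tm,
                               stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  paths <- list()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths$genes_bed <- file.path(dir, "genes.bed")
    utils::write.table(genes[c("chrom", "start", "end", "gene_id")],
                       paths$genes_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths$terms_tsv <- file.path(dir, "terms.tsv")
    utils::write.table(terms, paths$terms_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  c(list(genes = genes, terms = terms,
         truth = list(planted_terms = planted_terms,
                      sweep_genes = genes$gene_id[in_sweep])),
    paths)
}

#' Simulate genotypes with geometrically decaying linkage disequilibrium
#'
#' Haplotypes follow a two-state Markov chain along equally spaced sites:
#' the allele at each site copies the previous one and flips with a fixed
#' probability, giving inter-site dosage correlation
#' `(1 - 2 flip)^(d / spacing)` and hence an r-squared decay curve with a
#' known half-decay distance.
#'
#' @param n_samples diploid samples.
#' @param n_sites equally spaced sites.
#' @param spacing_bp distance between adjacent sites.
#' @param flip per-step flip probability in (0, 0.5).
#' @param seed optional seed.
#' @param chrom chromosome name.
#' @return List with `gm` (a [geno_matrix()]) and `half_decay_bp`, the
#'   distance at which expected r-squared halves.
#' @export
simulate_ld_genotypes <- function(n_samples = 60, n_sites = 80,
                                  spacing_bp = 1000L, flip = 0.02,
                                  seed = NULL, chrom = "chr1") {
  stopifnot(flip > 0, flip < 0.5)
  if (!is.null(seed)) set.seed(seed)
  n_hap <- 2L * n_samples
  H <- matrix(0L, n_hap, n_sites)
  H[, 1] <- stats::rbinom(n_hap, 1L, 0.5)
  for (j in 2:n_sites) {
    flips <- stats::rbinom(n_hap, 1L, flip)
    H[, j] <- ifelse(flips == 1L, 1L - H[, j - 1], H[, j - 1])
  }
  G <- H[seq(1, n_hap, by = 2), ] + H[seq(2, n_hap, by = 2), ]
  rownames(G) <- sprintf("s%03d", seq_len(n_samples))
  gm <- geno_matrix(G, seq_len(n_sites) * spacing_bp, chrom)
  # r2(d) = (1-2f)^(2 d / spacing); half of the maximum r2 (at d = spacing)
  rho <- (1 - 2 * flip)
  half_decay <- spacing_bp * (log(0.5) + 2 * log(rho)) / (2 * log(rho))
  list(gm = gm, half_decay_bp = half_decay)
}
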