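#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of HWE for biallelic genotype counts: the p-value
#' sums the probabilities of all heterozygote configurations (given the
#' observed allele counts) that are no more probable than the observed one
#' (the standard two-sided exact test of Wigginton et al. 2005). Computed in
#' log space.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts, total `>= 1`.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  N <- n_AA + n_Aa + n_aa
  if (N < 1) stop("need at least one genotyped sample")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | nA, N) up to a shared constant:
  #   N! / (nAA! nAa! naa!) * 2^nAa
  logp <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    AA <- N - aa - h
    h * log(2) - lfactorial(AA) - lfactorial(h) - lfactorial(aa)
  }, numeric(1))
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Composite (genotype-correlation) r-squared for one site pair
#'
#' The squared Pearson correlation of the diploid dosages at two sites over
#' the jointly genotyped samples -- the standard composite measure of
#' linkage disequilibrium for unphased data. Invariant to swapping allele
#' labels at either site.
#'
#' @param g1,g2 integer dosage vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA` if fewer than two jointly
#'   genotyped samples remain or either site is monomorphic among them.
#' @export
r2_pair <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD configuration
#'
#' Site and sample filters plus binning parameters for the decay curve,
#' mirroring common Haploview-style settings: minimum minor allele
#' frequency, HWE exact-test cutoff, maximum per-sample missingness, minimum
#' per-site genotyping rate, and a maximum pair distance.
#'
#' @param max_distance_kb maximum pair distance in kb. Default 1000.
#' @param min_maf minimum minor allele frequency (sites below are dropped).
#'   Default 0.05.
#' @param hwe_cutoff drop sites with HWE exact p below this. Default 0.001.
#' @param missing_cutoff drop samples with a missing-genotype fraction above
#'   this. Default 0.5.
#' @param min_geno minimum per-site genotyping rate. Default 0.6.
#' @param bin_width_bp distance-bin width for the decay curve. Default 1000.
#' @return List of class `ld_config`.
#' @export
ld_config <- function(max_distance_kb = 1000, min_maf = 0.05,
                      hwe_cutoff = 0.001, missing_cutoff = 0.5,
                      min_geno = 0.6, bin_width_bp = 1000) {
  stopifnot(max_distance_kb > 0, min_maf >= 0, min_maf <= 0.5,
            hwe_cutoff >= 0, hwe_cutoff <= 1, missing_cutoff >= 0,
            missing_cutoff <= 1, min_geno >= 0, min_geno <= 1,
            bin_width_bp > 0)
  structure(list(max_distance_kb = max_distance_kb, min_maf = min_maf,
                 hwe_cutoff = hwe_cutoff, missing_cutoff = missing_cutoff,
                 min_geno = min_geno, bin_width_bp = bin_width_bp),
            class = "ld_config")
}

#' Binned LD-decay curve and half-decay distance
#'
#' Filters samples (missingness) and sites (MAF, genotyping rate, HWE), then
#' scores every remaining intra-chromosome site pair within the maximum
#' distance with the composite r-squared, bins pairs by distance and averages
#' r-squared per bin. The half-decay distance is the smallest bin midpoint at
#' which the mean r-squared has dropped to half of the curve's maximum
#' (`NA` when never reached).
#'
#' @param gm a [geno_matrix()] (typically one population's samples).
#' @param cfg an [ld_config()].
#' @return List with `curve` (data.frame `mid_bp`, `mean_r2`, `n_pairs`),
#'   `half_decay_bp`, `n_sites_used`, `n_samples_used`, `n_pairs`.
#' @export
ld_decay <- function(gm, cfg = ld_config()) {
  G <- gm$G
  miss_frac <- rowMeans(is.na(G))
  keep_s <- miss_frac <= cfg$missing_cutoff
  G <- G[keep_s, , drop = FALSE]
  sc <- site_counts(G)
  maf <- ifelse(sc$n > 0, pmin(sc$alt / sc$n, 1 - sc$alt / sc$n), 0)
  geno_rate <- colMeans(!is.na(G))
  keep <- maf >= cfg$min_maf & geno_rate >= cfg$min_geno
  if (cfg$hwe_cutoff > 0) {
    hwe_p <- rep(1, ncol(G))
    for (j in which(keep)) {
      g <- G[, j]
      hwe_p[j] <- hwe_exact_p(sum(g == 0L, na.rm = TRUE),
                              sum(g == 1L, na.rm = TRUE),
                              sum(g == 2L, na.rm = TRUE))
    }
    keep <- keep & hwe_p >= cfg$hwe_cutoff
  }
  pos <- gm$positions[keep]
  G <- G[, keep, drop = FALSE]
  empty_curve <- data.frame(mid_bp = numeric(0), mean_r2 = numeric(0),
                            n_pairs = integer(0))
  if (ncol(G) < 2) {
    warning("fewer than two sites survive the LD filters")
    return(list(curve = empty_curve, half_decay_bp = NA_real_,
                n_sites_used = ncol(G), n_samples_used = nrow(G),
                n_pairs = 0L))
  }
  r2m <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
  dist <- abs(outer(pos, pos, "-"))
  ut <- upper.tri(dist)
  sel <- ut & dist <= cfg$max_distance_kb * 1000 & !is.na(r2m)
  d <- dist[sel]
  r2 <- r2m[sel]
  if (!length(d)) {
    warning("no evaluable site pairs within the maximum distance")
    return(list(curve = empty_curve, half_decay_bp = NA_real_,
                n_sites_used = ncol(G), n_samples_used = nrow(G),
                n_pairs = 0L))
  }
  bin <- floor(d / cfg$bin_width_bp)
  agg <- tapply(r2, bin, mean)
  cnt <- tapply(r2, bin, length)
  mids <- (as.numeric(names(agg)) + 0.5) * cfg$bin_width_bp
  o <- order(mids)
  curve <- data.frame(mid_bp = mids[o], mean_r2 = as.numeric(agg)[o],
                      n_pairs = as.integer(cnt)[o])
  half <- max(curve$mean_r2) / 2
  below <- which(curve$mean_r2 <= half)
  list(curve = curve,
       half_decay_bp = if (length(below)) curve$mid_bp[min(below)] else NA_real_,
       n_sites_used = ncol(G), n_samples_used = nrow(G),
       n_pairs = length(d))
}
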