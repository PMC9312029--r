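#' Per-site allele statistics
#'
#' Counts alleles at a single site from diploid dosages, using only the
#' genotyped (non-missing) samples.
#'
#' @param g integer vector of dosages in `{0, 1, 2, NA}`.
#' @return A list with `n` (number of called alleles, `2 x` genotyped
#'   samples), `alt` (alternate allele count) and `maf` (minor allele
#'   frequency). All `NA` when no sample is genotyped.
#' @export
site_allele_stats <- function(g) {
  called <- !is.na(g)
  if (!any(called)) return(list(n = NA_integer_, alt = NA_integer_,
                                maf = NA_real_))
  n <- 2L * sum(called)
  alt <- as.integer(sum(g[called]))
  p <- alt / n
  list(n = n, alt = alt, maf = min(p, 1 - p))
}

# vectorised site summaries over a matrix (samples x sites): called allele
# count n, alt count, and heterozygote count per site. ploidy = 1 treats
# rows as haplotypes (entries 0/1, one allele each).
site_counts <- function(G, ploidy = 2L) {
  called <- !is.na(G)
  n <- as.integer(ploidy) * colSums(called)
  Gz <- G
  Gz[!called] <- 0L
  alt <- colSums(Gz)
  het <- if (ploidy == 2L) colSums(Gz == 1L) else rep(0L, ncol(G))
  list(n = n, alt = alt, het = het)
}

#' Nucleotide diversity of a window
#'
#' Per-site pairwise diversity computed from allele frequencies with the
#' `n/(n-1)` small-sample correction, summed over sites and divided by the
#' effective window length. Monomorphic sites contribute zero; sites with
#' fewer than two called alleles are skipped.
#'
#' @param G dosage matrix (samples x sites) or a [geno_matrix()].
#' @param L effective window length in bp (`> 0`).
#' @param ploidy 2 for diploid dosages (default), 1 for a 0/1 haplotype
#'   matrix.
#' @return Per-site nucleotide diversity (a single number).
#' @export
theta_pi <- function(G, L, ploidy = 2L) {
  if (L <= 0) stop("window length L must be > 0")
  pi_total(G, ploidy) / L
}

# sum over sites of 2*p*(1-p)*n/(n-1) -- the unnormalised pi ingredient
# shared by theta_pi and Tajima's D
pi_total <- function(G, ploidy = 2L) {
  if (inherits(G, "geno_matrix")) G <- G$G
  G <- as.matrix(G)
  if (ncol(G) == 0L) return(0)
  sc <- site_counts(G, ploidy)
  ok <- sc$n >= 2L
  if (!any(ok)) return(0)
  n <- sc$n[ok]
  p <- sc$alt[ok] / n
  sum(2 * p * (1 - p) * n / (n - 1))
}

#' Watterson's theta
#'
#' `theta_w = S / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites.
#' @param n number of sampled alleles (`>= 2`).
#' @param L window length in bp (`> 0`).
#' @return Per-site Watterson estimator.
#' @export
theta_w <- function(S, n, L) {
  if (n < 2) stop("need at least n = 2 alleles")
  if (L <= 0) stop("window length L must be > 0")
  S / (harmonic_number(n - 1) * L)
}

harmonic_number <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))

#' Constants of Tajima's D
#'
#' The sample-size-dependent constants `a1, a2, b1, b2, c1, c2, e1, e2` of
#' Tajima's (1989) test statistic.
#'
#' @param n number of sampled alleles (`>= 2`).
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need at least n = 2 alleles")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Normalised difference between the mean-pairwise-difference and
#' segregating-sites estimators of theta. `NA` when there are no segregating
#' sites.
#'
#' @param S number of segregating sites.
#' @param pi_tot sum of per-site pairwise diversity over the window (i.e.
#'   `theta_pi * L`), not divided by length.
#' @param n number of sampled alleles.
#' @return Tajima's D, or `NA` if `S == 0`.
#' @export
tajimas_d <- function(S, pi_tot, n) {
  if (n < 2) stop("need at least n = 2 alleles")
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_tot - S / k$a1) / denom
}

#' Windowed diversity summary for one population
#'
#' Computes the segregating-site count, theta-pi, Watterson's theta and
#' Tajima's D for a dosage matrix slice. With missing data the allele count
#' varies across sites; Tajima's D and Watterson's theta use the modal allele
#' count of the window's polymorphic-capable sites.
#'
#' @param G dosage matrix (samples x sites) or [geno_matrix()].
#' @param L effective window length in bp.
#' @param ploidy 2 for diploid dosages (default), 1 for a 0/1 haplotype
#'   matrix.
#' @return List with `S`, `theta_pi`, `theta_w`, `tajimas_d`, `n_eff`
#'   (modal allele count), `pi_total`, `n_sites`.
#' @export
diversity_stats <- function(G, L, ploidy = 2L) {
  if (inherits(G, "geno_matrix")) G <- G$G
  G <- as.matrix(G)
  if (L <= 0) stop("window length L must be > 0")
  if (ncol(G) == 0L)
    return(list(S = 0L, theta_pi = 0, theta_w = 0, tajimas_d = NA_real_,
                n_eff = NA_integer_, pi_total = 0, n_sites = 0L))
  sc <- site_counts(G, ploidy)
  ok <- sc$n >= 2L
  S <- sum(ok & sc$alt > 0L & sc$alt < sc$n)
  ptot <- pi_total(G, ploidy)
  n_eff <- if (any(ok)) modal_value(sc$n[ok]) else NA_integer_
  tw <- if (!is.na(n_eff) && n_eff >= 2L) theta_w(S, n_eff, L) else NA_real_
  td <- if (!is.na(n_eff) && n_eff >= 2L) tajimas_d(S, ptot, n_eff) else NA_real_
  list(S = as.integer(S), theta_pi = ptot / L, theta_w = tw, tajimas_d = td,
       n_eff = n_eff, pi_total = ptot, n_sites = ncol(G))
}

modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Weir-Cockerham Fst for two populations
#'
#' Per-site variance components `a` (between populations), `b` (between
#' individuals within populations) and `c` (within individuals,
#' heterozygosity) following Weir & Cockerham (1984), combined over sites as
#' a ratio of sums: `Fst = sum(a) / sum(a + b + c)`. Negative estimates are
#' retained. Sites where either population has no genotyped individual, or
#' with fewer than two genotyped individuals overall, are skipped.
#'
#' @param gm a two-population [geno_matrix()], or a plain dosage matrix with
#'   `pops` supplied.
#' @param pops named character vector sample -> population (ignored when `gm`
#'   is a `geno_matrix`).
#' @return List with `fst`, `numerator_sum`, `denominator_sum` and
#'   `n_sites_used`. `fst` is `NA` when no site is usable or the denominator
#'   is zero.
#' @export
fst_weir_cockerham <- function(gm, pops = NULL) {
  if (inherits(gm, "geno_matrix")) {
    G <- gm$G
    pops <- gm$pops
    labs <- pop_labels(gm)
  } else {
    G <- as.matrix(gm)
    if (is.null(pops)) stop("pops required for a plain matrix")
    pops <- pops[rownames(G)]
    labs <- sort(unique(pops))
    if (length(labs) != 2L) stop("exactly two populations required")
  }
  comp <- wc_site_components(G[pops == labs[1], , drop = FALSE],
                             G[pops == labs[2], , drop = FALSE])
  num <- sum(comp$a[comp$ok])
  den <- sum((comp$a + comp$b + comp$c)[comp$ok])
  fst <- if (sum(comp$ok) == 0L || den == 0) NA_real_ else num / den
  list(fst = fst, numerator_sum = num, denominator_sum = den,
       n_sites_used = sum(comp$ok))
}

# vectorised WC (1984) two-population variance components per site.
# G1, G2: dosage matrices of the two populations over the same sites.
wc_site_components <- function(G1, G2) {
  c1 <- site_counts(G1)
  c2 <- site_counts(G2)
  n1 <- c1$n / 2  # genotyped individuals per site
  n2 <- c2$n / 2
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1
  p1 <- ifelse(c1$n > 0, c1$alt / c1$n, NA_real_)
  p2 <- ifelse(c2$n > 0, c2$alt / c2$n, NA_real_)
  h1 <- ifelse(n1 > 0, c1$het / n1, NA_real_)
  h2 <- ifelse(n2 > 0, c2$het / n2, NA_real_)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  # monomorphic sites contribute zero to both sums; keep them in 'ok' so the
  # ratio-of-sums matches per-site accumulation exactly
  list(a = a, b = b, c = cc, ok = ok)
}

#' Hudson's Fst for two populations
#'
#' Alternative estimator (ratio of sums of Hudson numerator/denominator, as
#' in Bhatia et al. 2013) for sensitivity analysis alongside
#' [fst_weir_cockerham()].
#'
#' @inheritParams fst_weir_cockerham
#' @return List with `fst`, `numerator_sum`, `denominator_sum`.
#' @export
fst_hudson <- function(gm, pops = NULL) {
  if (inherits(gm, "geno_matrix")) {
    G <- gm$G; pops <- gm$pops; labs <- pop_labels(gm)
  } else {
    G <- as.matrix(gm)
    pops <- pops[rownames(G)]
    labs <- sort(unique(pops))
  }
  s1 <- site_counts(G[pops == labs[1], , drop = FALSE])
  s2 <- site_counts(G[pops == labs[2], , drop = FALSE])
  ok <- s1$n >= 2 & s2$n >= 2
  p1 <- s1$alt[ok] / s1$n[ok]
  p2 <- s2$alt[ok] / s2$n[ok]
  n1 <- s1$n[ok]; n2 <- s2$n[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- if (!any(ok) || sum(den) == 0) NA_real_ else sum(num) / sum(den)
  list(fst = fst, numerator_sum = sum(num), denominator_sum = sum(den))
}

#' Log2 diversity ratio
#'
#' `log2((pi_a + eps) / (pi_b + eps))`; the pseudocount keeps windows swept
#' to zero diversity finite without reordering ranks. Antisymmetric under
#' swapping the two populations.
#'
#' @param pi_a,pi_b per-site diversities (`>= 0`).
#' @param eps pseudocount (default `1e-8` per site).
#' @return log2 ratio.
#' @export
log2_pi_ratio <- function(pi_a, pi_b, eps = 1e-8) {
  if (any(pi_a < 0, na.rm = TRUE) || any(pi_b < 0, na.rm = TRUE))
    stop("diversities must be non-negative")
  if (eps <= 0) stop("pseudocount must be positive")
  log2((pi_a + eps) / (pi_b + eps))
}
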