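# Independent brute-force oracles used to freeze expected values.
# Each is deliberately written as a direct transcription of the defining
# formula (scalar loops, explicit enumeration), not sharing code with the
# package implementations it checks.

# mean pairwise difference per site pair over haplotypes, divided by L
oracle_pi_pairwise <- function(H, L) {
  n <- nrow(H)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(H[i, ] != H[j, ])
  tot / choose(n, 2) / L
}

# scalar per-site Weir-Cockerham components, accumulated explicitly
oracle_wc_fst <- function(G1, G2) {
  num <- den <- 0
  for (s in seq_len(ncol(G1))) {
    g1 <- G1[, s][!is.na(G1[, s])]
    g2 <- G2[, s][!is.na(G2[, s])]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 1 || n2 < 1 || (n1 + n2) / 2 <= 1) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# direct variance decomposition for Vst (population variances, denominator n)
oracle_vst <- function(cn, pops) {
  pv <- function(x) sum((x - mean(x))^2) / length(x)
  vt <- pv(cn)
  labs <- unique(pops)
  vs <- 0
  for (l in labs) {
    x <- cn[pops == l]
    vs <- vs + pv(x) * length(x)
  }
  vs <- vs / length(cn)
  if (vt == 0) return(NA_real_)
  max(0, (vt - vs) / vt)
}

# upper-tail hypergeometric probability by explicit PMF summation
oracle_hypergeom_upper <- function(x, K, n, N) {
  tot <- 0
  for (i in x:min(K, n))
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  tot / choose(N, n)
}

# exact HWE p by enumerating all heterozygote configurations with the
# observed allele counts; probabilities from the multinomial/2^h formula
oracle_hwe <- function(nAA, nAa, naa) {
  N <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * N - nA
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(hets, function(h) {
    raa <- (rare - h) / 2
    com <- N - raa - h
    exp(lchoose(N, com) + lchoose(N - com, h) + h * log(2))
  })
  pr <- pr / sum(pr)
  pobs <- pr[hets == nAa]
  sum(pr[pr <= pobs * (1 + 1e-12)])
}

# haplotype-count r^2 for homozygous-only dosage vectors (each diploid is
# two copies of one haplotype)
oracle_r2_haplotype <- function(g1, g2) {
  h1 <- g1 / 2
  h2 <- g2 / 2
  p11 <- mean(h1 == 1 & h2 == 1)
  pA <- mean(h1); pB <- mean(h2)
  d <- p11 - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Tajima constants re-derived independently (loops, no shared helpers)
oracle_tajima_constants <- function(n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  list(a1 = a1, a2 = a2,
       e1 = c1 / a1, e2 = c2 / (a1 * a1 + a2))
}

# random dosage matrix with optional missingness
random_dosage_matrix <- function(n_samples, n_sites, miss = 0) {
  G <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
              n_samples, n_sites)
  if (miss > 0) G[runif(length(G)) < miss] <- NA
  rownames(G) <- sprintf("s%02d", seq_len(n_samples))
  G
}
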