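test_that("site allele counting handles typical, boundary and all-missing sites", {
  s <- site_allele_stats(c(0L, 0L, 1L, 2L))
  expect_equal(s$n, 8L)
  expect_equal(s$alt, 3L)
  expect_equal(s$maf, 3 / 8)
  expect_true(all(is.na(unlist(site_allele_stats(c(NA, NA))))))
  expect_equal(site_allele_stats(c(0L, NA, 2L))$n, 4L)
})

test_that("theta_pi matches the single-pair definition and zero cases", {
  # two haploid-equivalent samples differing at 3 of 100 positions
  H <- matrix(0L, 2, 3)
  H[2, ] <- 1L
  expect_equal(theta_pi(H, 100, ploidy = 1), 0.03)
  expect_equal(theta_pi(matrix(2L, 4, 10), 100), 0)  # monomorphic
  expect_error(theta_pi(H, 0), "L must be > 0")
})

test_that("theta_pi equals the brute-force pairwise-difference oracle on haplotypes", {
  withr::local_seed(101)
  for (rep in 1:25) {
    H <- matrix(rbinom(8 * 30, 1, runif(1, 0.1, 0.9)), 8, 30)
    expect_equal(theta_pi(H, 30, ploidy = 1), oracle_pi_pairwise(H, 30),
                 tolerance = 1e-12)
  }
})

test_that("theta_w follows the harmonic normalisation", {
  expect_equal(theta_w(0, 10, 100), 0)
  expect_equal(theta_w(7, 2, 100), 7 / 100)  # a1 = 1 for n = 2
  expect_equal(theta_w(9, 10, 1000), 9 / (sum(1 / (1:9)) * 1000))
  expect_equal(theta_w(9, 10, 1000), 0.003181372, tolerance = 1e-6)
  expect_error(theta_w(3, 1, 100), "n = 2")
})

test_that("Tajima constants match an independent re-derivation", {
  for (n in c(4, 10, 16, 50)) {
    k <- tajima_constants(n)
    o <- oracle_tajima_constants(n)
    expect_equal(k$a1, o$a1, tolerance = 1e-12)
    expect_equal(k$a2, o$a2, tolerance = 1e-12)
    expect_equal(k$e1, o$e1, tolerance = 1e-12)
    expect_equal(k$e2, o$e2, tolerance = 1e-12)
  }
  expect_equal(tajima_constants(10)$a1, 2.828968, tolerance = 1e-6)
  expect_equal(tajima_constants(10)$a2, 1.539768, tolerance = 1e-6)
  expect_true(is.na(tajimas_d(0, 0, 10)))
})

test_that("pi and theta_w are invariant to sample order and allele-label swap", {
  withr::local_seed(7)
  G <- random_dosage_matrix(10, 40, miss = 0.1)
  perm <- sample(nrow(G))
  expect_equal(theta_pi(G, 40), theta_pi(G[perm, ], 40))
  expect_equal(theta_pi(G, 40), theta_pi(2L - G, 40))
  d1 <- diversity_stats(G, 40)
  d2 <- diversity_stats(2L - G, 40)
  expect_equal(d1$S, d2$S)
  expect_equal(d1$theta_w, d2$theta_w)
})

test_that("Weir-Cockerham Fst hits the fixed-difference and no-differentiation bounds", {
  G <- rbind(matrix(0L, 5, 20), matrix(2L, 3, 20))
  rownames(G) <- paste0("s", 1:8)
  pops <- setNames(rep(c("a", "b"), c(5, 3)), rownames(G))
  expect_equal(fst_weir_cockerham(G, pops)$fst, 1)
  # identical genotype counts in both populations -> sum(a) <= 0
  blk <- matrix(rep(c(0L, 1L, 2L, 1L), each = 4), 4, 4)
  G2 <- rbind(blk, blk)
  rownames(G2) <- paste0("s", 1:8)
  pops2 <- setNames(rep(c("a", "b"), each = 4), rownames(G2))
  expect_lte(fst_weir_cockerham(G2, pops2)$fst, 0)
})

test_that("ratio-of-sums Fst equals the per-site-components oracle", {
  withr::local_seed(42)
  for (rep in 1:20) {
    G <- random_dosage_matrix(12, 50, miss = 0.05)
    pops <- setNames(rep(c("a", "b"), c(7, 5)), rownames(G))
    got <- fst_weir_cockerham(G, pops)$fst
    want <- oracle_wc_fst(G[1:7, ], G[8:12, ])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Fst recovers the generating Balding-Nichols differentiation", {
  withr::local_seed(12)
  F <- 0.1; ns <- 5000; nd <- 25
  p <- runif(ns, 0.05, 0.95)
  G <- matrix(NA_integer_, 2 * nd, ns)
  for (popi in 1:2) {
    pf <- rbeta(ns, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    for (r in 1:nd) G[(popi - 1) * nd + r, ] <- rbinom(ns, 2, pf)
  }
  rownames(G) <- paste0("s", 1:(2 * nd))
  pops <- setNames(rep(c("a", "b"), each = nd), rownames(G))
  expect_equal(fst_weir_cockerham(G, pops)$fst, F, tolerance = 0.02)
  # Hudson estimator agrees to the same tolerance
  expect_equal(fst_hudson(G, pops)$fst, F, tolerance = 0.02)
})

test_that("log2 pi-ratio is antisymmetric with the expected fixed points", {
  expect_equal(log2_pi_ratio(0.004, 0.004), 0)
  expect_equal(log2_pi_ratio(0.02, 0.01), 1, tolerance = 1e-5)
  expect_equal(log2_pi_ratio(0.003, 0.0007),
               -log2_pi_ratio(0.0007, 0.003))
  expect_error(log2_pi_ratio(-1, 1), "non-negative")
})

test_that("windowed diversity handles empty windows and missing data", {
  d <- diversity_stats(matrix(integer(0), 4, 0), 100)
  expect_equal(d$S, 0L)
  expect_equal(d$theta_pi, 0)
  expect_true(is.na(d$tajimas_d))
  # modal allele count with scattered missingness
  G <- random_dosage_matrix(6, 30, miss = 0.2)
  d2 <- diversity_stats(G, 30)
  expect_true(d2$n_eff <= 12 && d2$n_eff >= 2)
})
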