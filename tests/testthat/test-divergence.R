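test_that("IBS distance hits identity and opposite-homozygote bounds", {
  G <- rbind(a = c(0L, 1L, 2L, 0L), b = c(0L, 1L, 2L, 0L),
             c = c(2L, 1L, 0L, 2L))
  D <- ibs_distance(G)
  expect_equal(D["a", "b"], 0)
  expect_equal(unname(diag(D)), rep(0, 3))
  G2 <- rbind(a = c(0L, 0L, 0L), b = c(2L, 2L, 2L))
  expect_equal(ibs_distance(G2)["a", "b"], 1)
})

test_that("IBS distance equals the per-site hand computation and flags empty pairs", {
  withr::local_seed(41)
  G <- random_dosage_matrix(6, 25, miss = 0.15)
  D <- ibs_distance(G)
  for (i in 1:5) for (j in (i + 1):6) {
    ok <- !is.na(G[i, ]) & !is.na(G[j, ])
    expect_equal(D[i, j], sum(abs(G[i, ok] - G[j, ok]) / 2) / sum(ok))
  }
  G[1, ] <- NA; G[1, 1] <- 0L
  G[2, ] <- NA; G[2, 2] <- 0L
  expect_error(ibs_distance(G), "share no genotyped site")
})

test_that("three-taxon neighbor joining solves the three-point equations", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D)
  # lx = (5 + 9 - 10)/2 = 2, ly = 3, lz = 7
  len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                       tr$edge[, 2])], tr$tip.label)
  expect_equal(len[c("x", "y", "z")], c(x = 2, y = 3, z = 7))
})

test_that("neighbor joining reconstructs random additive trees exactly", {
  withr::local_seed(42)
  for (i in 1:25) {
    tr <- ape::rtree(6)
    D <- ape::cophenetic.phylo(tr)
    nj2 <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(nj2)), 0)
    D2 <- ape::cophenetic.phylo(nj2)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
  }
})

test_that("neighbor joining agrees with the reference implementation on random matrices", {
  withr::local_seed(43)
  for (i in 1:10) {
    X <- matrix(runif(7 * 20), 7)
    rownames(X) <- letters[1:7]
    D <- as.matrix(dist(X))
    expect_equal(phangorn::RF.dist(neighbor_joining(D), ape::nj(D)), 0)
  }
})

test_that("neighbor joining is deterministic and label-permutation invariant", {
  withr::local_seed(44)
  D <- as.matrix(dist(matrix(runif(12), 6)))
  rownames(D) <- colnames(D) <- paste0("t", 1:6)
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  perm <- c(4, 2, 6, 1, 3, 5)
  t3 <- neighbor_joining(D[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t3), 0)
  # contract errors
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(neighbor_joining(Dbad), "symmetric")
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(neighbor_joining(Dna), "NA")
})

test_that("midpoint rooting preserves leaf-to-leaf path lengths", {
  withr::local_seed(45)
  tr <- ape::rtree(6)
  D <- ape::cophenetic.phylo(tr)
  rooted <- neighbor_joining(D, root = "midpoint")
  D2 <- ape::cophenetic.phylo(rooted)[rownames(D), colnames(D)]
  expect_lt(max(abs(D2 - D)), 1e-8)
})

test_that("newick output round-trips through ape", {
  D <- as.matrix(dist(matrix(1:12, 6)))
  rownames(D) <- colnames(D) <- paste0("t", 1:6)
  tr <- neighbor_joining(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(phangorn::RF.dist(back, tr), 0)
})

test_that("PCA separates simulated populations and handles edge cases", {
  cfg <- sim_config(seed = 46, n_windows = 20, sites_per_window = 25,
                    background_fst = 0.3, sweep_n = 0,
                    n_pop = c(popA = 10L, popB = 10L))
  sim <- simulate_two_pop_vcf(cfg, dir = withr::local_tempdir())
  gm <- geno_matrix(sim$dosages, sim$positions, cfg$chrom, pops = sim$pops)
  pc <- genotype_pca(gm, k = 2)
  pc1 <- pc$scores[, 1]
  grp <- sim$pops[rownames(pc$scores)]
  # PC1 silhouette: every sample closer to its own population mean
  m <- tapply(pc1, grp, mean)
  own <- abs(pc1 - m[grp])
  other <- abs(pc1 - ifelse(grp == names(m)[1], m[2], m[1]))
  expect_gt(mean(own < other), 0.9)
  expect_true(all(abs(colSums(pc$scores)) < 1e-6))  # centered scores
  expect_lte(sum(pc$explained), 1)
  # duplicate sample -> identical coordinates
  G <- gm$G
  G2 <- rbind(G, dup = G[1, ])
  pc2 <- genotype_pca(G2, k = 2)
  expect_equal(pc2$scores["dup", ], pc2$scores[1, ],
               ignore_attr = TRUE)
  expect_error(genotype_pca(matrix(1L, 3, 4), k = 2), "polymorphic")
  expect_warning(genotype_pca(gm, k = 50), "reduced")
})
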