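#' Identity-by-state distance matrix
#'
#' `d(i, j)` is the mean over jointly genotyped sites of
#' `|dosage_i - dosage_j| / 2`: 0 for identical genotypes everywhere, 1 for
#' opposite homozygotes everywhere.
#'
#' @param gm a [geno_matrix()] or dosage matrix (samples x sites).
#' @return Symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
ibs_distance <- function(gm) {
  G <- if (inherits(gm, "geno_matrix")) gm$G else as.matrix(gm)
  n <- nrow(G)
  if (n < 2) stop("need at least two samples")
  D <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  bad <- character(0)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    ok <- !is.na(G[i, ]) & !is.na(G[j, ])
    if (!any(ok)) {
      bad <- c(bad, paste(rownames(G)[i], rownames(G)[j], sep = "/"))
      D[i, j] <- D[j, i] <- NA_real_
    } else {
      D[i, j] <- D[j, i] <- mean(abs(G[i, ok] - G[j, ok])) / 2
    }
  }
  if (length(bad))
    stop("sample pair(s) share no genotyped site: ",
         paste(bad, collapse = ", "))
  D
}

#' Neighbor-joining tree
#'
#' Classic Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.
#' On additive distances the generating topology is recovered with exact
#' branch lengths. Ties in Q are broken by the lexicographically smallest
#' pair of node labels (an internal node is labelled by the smallest leaf
#' beneath it), making the output deterministic. Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch.
#'
#' @param D symmetric distance matrix with labels (e.g. from
#'   [ibs_distance()]); no `NA`s.
#' @param root `"none"` (unrooted, default) or `"midpoint"`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
neighbor_joining <- function(D, root = c("none", "midpoint")) {
  root <- match.arg(root)
  D <- as.matrix(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(nrow(D)))
  if (nrow(D) < 3) stop("need at least three taxa")
  if (anyNA(D)) stop("distance matrix contains NA")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  nwk <- labels          # growing newick fragment per active node
  minlab <- labels       # smallest leaf label beneath each active node
  repeat {
    r <- nrow(D)
    if (r == 3) break
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      p <- sort(c(minlab[ij[1]], minlab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    bl <- clamp_branch_pair(li, lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], bl[1], nwk[j], bl[2])
    new_lab <- min(minlab[i], minlab[j])
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    minlab <- c(minlab[keep], new_lab)
    rownames(D) <- colnames(D) <- minlab
  }
  # resolve the final three-node star with the closed-form lengths
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- clamp_branch_star(c(l1, l2, l3))
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[1], ls[1], nwk[2], ls[2], nwk[3], ls[3])
  tree <- ape::read.tree(text = txt)
  if (root == "midpoint") tree <- phangorn::midpoint(tree)
  tree
}

# clamp a negative length in a cherry to 0, moving the deficit to the sister
clamp_branch_pair <- function(a, b) {
  if (a < 0) { b <- b + a; a <- 0 }
  if (b < 0) { a <- max(0, a + b); b <- 0 }
  c(a, b)
}

clamp_branch_star <- function(l) {
  for (k in seq_along(l)) if (l[k] < 0) {
    others <- setdiff(seq_along(l), k)
    l[others] <- l[others] + l[k] / 2
    l[k] <- 0
  }
  pmax(l, 0)
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Genotype principal component analysis
#'
#' Column-centers the dosage matrix over polymorphic sites (optionally
#' Patterson-style frequency standardization), mean-imputes missing entries,
#' and decomposes. Coordinates are orthogonal; explained-variance fractions
#' sum to at most 1.
#'
#' @param gm a [geno_matrix()] or dosage matrix (samples x sites).
#' @param k number of components to return (truncated with a warning when
#'   `k > samples - 1`).
#' @param scale `"center"` (default) or `"patterson"`
#'   (divide by `sqrt(p * (1 - p))`).
#' @return List with `scores` (samples x k), `explained` (variance
#'   fractions) and `n_sites_used`.
#' @export
genotype_pca <- function(gm, k = 3, scale = c("center", "patterson")) {
  scale <- match.arg(scale)
  G <- if (inherits(gm, "geno_matrix")) gm$G else as.matrix(gm)
  if (nrow(G) < 2) stop("need at least two samples")
  v <- apply(G, 2L, stats::var, na.rm = TRUE)
  poly <- !is.na(v) & v > 0
  if (!any(poly)) stop("no polymorphic site; PCA undefined")
  p <- colMeans(G, na.rm = TRUE) / 2
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(G, 2L, 2 * p, "-")
  if (scale == "patterson") X <- sweep(X, 2L, sqrt(p * (1 - p)), "/")
  X[is.na(X)] <- 0
  kmax <- nrow(X) - 1L
  if (k > kmax) {
    warning("k reduced to ", kmax, " (samples - 1)")
    k <- kmax
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], n_sites_used = ncol(X))
}
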