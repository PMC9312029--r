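#' Build a genotype dosage matrix
#'
#' The central substrate of all SNP statistics: a samples-by-sites matrix of
#' diploid alternate-allele dosages (0, 1, 2, or `NA` for missing) on a single
#' chromosome, with 1-based site positions, ref/alt alleles and a
#' sample-to-population assignment.
#'
#' @param G integer matrix, samples in rows, sites in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param positions integer vector of 1-based positions (VCF convention),
#'   strictly increasing, one per column of `G`.
#' @param chrom single chromosome identifier.
#' @param samples character vector of sample ids (defaults to `rownames(G)`).
#' @param pops named character vector mapping each sample to a population
#'   label, or `NULL` when no population structure is needed.
#' @param ref,alt optional character vectors of reference / alternate alleles
#'   per site.
#'
#' @return An object of class `geno_matrix`: a list with elements `G`,
#'   `positions`, `chrom`, `samples`, `pops`, `ref`, `alt`.
#' @export
geno_matrix <- function(G, positions, chrom, samples = rownames(G),
                        pops = NULL, ref = NULL, alt = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(G)))
  if (length(positions) != ncol(G))
    stop("length(positions) must equal ncol(G)")
  positions <- as.integer(positions)
  if (ncol(G) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (any(positions < 1L)) stop("positions must be >= 1")
  bad <- G[!is.na(G)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be in {0, 1, 2, NA}")
  if (!is.null(pops)) {
    pops <- pops[samples]
    if (anyNA(pops))
      stop("every sample needs a population label: missing for ",
           paste(samples[is.na(pops)], collapse = ", "))
  }
  rownames(G) <- samples
  structure(list(G = G, positions = positions, chrom = as.character(chrom)[1],
                 samples = samples, pops = pops, ref = ref, alt = alt),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites on %s\n",
              nrow(x$G), ncol(x$G), x$chrom))
  if (!is.null(x$pops)) {
    tab <- table(x$pops)
    cat("populations:", paste(sprintf("%s (n=%d)", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$G)

# population labels in deterministic (sorted) order; errors unless exactly two
pop_labels <- function(gm) {
  if (is.null(gm$pops)) stop("genotype matrix has no population labels")
  labs <- sort(unique(gm$pops))
  if (length(labs) != 2L)
    stop("exactly two population labels required, got: ",
         paste(labs, collapse = ", "))
  if (any(table(gm$pops)[labs] == 0L)) stop("both populations must be non-empty")
  labs
}

# subset sites by column index, keeping metadata consistent
subset_sites <- function(gm, idx) {
  geno_matrix(gm$G[, idx, drop = FALSE], gm$positions[idx], gm$chrom,
              samples = gm$samples, pops = gm$pops,
              ref = if (!is.null(gm$ref)) gm$ref[idx],
              alt = if (!is.null(gm$alt)) gm$alt[idx])
}

# rows of G belonging to one population
pop_rows <- function(gm, pop) which(gm$pops == pop)
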