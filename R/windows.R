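#' Tile chromosomes into sliding windows
#'
#' Windows start at `0, step, 2*step, ...` (0-based half-open coordinates);
#' the last window is truncated at the chromosome end and kept only if it is
#' strictly longer than half the nominal window size, avoiding
#' high-variance window tails.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param size window size in bp.
#' @param step step between window starts in bp (`0 < step <= size`).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `eff_len`.
#' @export
make_windows <- function(chrom_lengths, size, step = size) {
  if (step <= 0 || size <= 0) stop("size and step must be positive")
  if (step > size) stop("step must not exceed window size")
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(0L, by = as.integer(step),
                  length.out = max(0L, ceiling(len / step)))
    starts <- starts[starts < len]
    ends <- pmin(starts + as.integer(size), as.integer(len))
    keep <- (ends - starts) > size / 2
    data.frame(chrom = rep(chr, sum(keep)), start = starts[keep],
               end = ends[keep], eff_len = ends[keep] - starts[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Shipped window-grid presets
#'
#' Two grids are used in the analyses this package supports: a 100 kb / 20 kb
#' grid for the log2 pi-ratio scan and a 40 kb / 20 kb grid for the joint
#' Fst / diversity scan.
#'
#' @param name `"pi_ratio_scan"` or `"fst_scan"`.
#' @return List with `size` and `step` in bp.
#' @export
scan_preset <- function(name = c("fst_scan", "pi_ratio_scan")) {
  switch(match.arg(name),
         pi_ratio_scan = list(size = 100000L, step = 20000L),
         fst_scan = list(size = 40000L, step = 20000L))
}

#' Windowed two-population scan
#'
#' Applies the per-window diversity and differentiation statistics to a
#' two-population genotype matrix over a set of windows. A SNP at 1-based
#' position `p` belongs to window `[start, end)` iff `start <= p - 1 < end`;
#' with overlapping windows a SNP contributes to every window covering it.
#' Population columns are suffixed with the sorted population labels.
#'
#' @param gm a two-population [geno_matrix()].
#' @param windows data.frame from [make_windows()] (rows on other
#'   chromosomes yield empty stats with a warning), or `NULL` to tile the
#'   span of the data with `size`/`step`.
#' @param size,step used when `windows` is `NULL`.
#' @param eps pseudocount for the log2 pi-ratio.
#' @return data.frame (one row per window): `chrom`, `start`, `end`,
#'   `eff_len`, `n_snps`, then per population `pi_*`, `theta_w_*`, `tajd_*`,
#'   `S_*`, plus `fst` and `log2_pi_ratio` (first sorted label over second).
#'   Population labels are stored in the `"pops"` attribute.
#' @export
scan_windows <- function(gm, windows = NULL, size = 40000L, step = 20000L,
                         eps = 1e-8) {
  labs <- pop_labels(gm)
  if (is.null(windows)) {
    len <- max(gm$positions)
    windows <- make_windows(stats::setNames(len, gm$chrom), size, step)
  }
  off <- windows$chrom != gm$chrom
  if (any(off))
    warning("windows on chromosome(s) absent from the genotype matrix: ",
            paste(unique(windows$chrom[off]), collapse = ", "))
  rows1 <- pop_rows(gm, labs[1])
  rows2 <- pop_rows(gm, labs[2])
  pos0 <- gm$positions - 1L  # 0-based site coordinates
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    idx <- if (w$chrom == gm$chrom)
      which(pos0 >= w$start & pos0 < w$end) else integer(0)
    Gw <- gm$G[, idx, drop = FALSE]
    d1 <- diversity_stats(Gw[rows1, , drop = FALSE], w$eff_len)
    d2 <- diversity_stats(Gw[rows2, , drop = FALSE], w$eff_len)
    fst <- if (length(idx))
      fst_weir_cockerham(Gw, gm$pops)$fst else NA_real_
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               eff_len = w$eff_len, n_snps = length(idx),
               pi_1 = d1$theta_pi, theta_w_1 = d1$theta_w,
               tajd_1 = d1$tajimas_d, S_1 = d1$S,
               pi_2 = d2$theta_pi, theta_w_2 = d2$theta_w,
               tajd_2 = d2$tajimas_d, S_2 = d2$S,
               fst = fst,
               log2_pi_ratio = log2_pi_ratio(d1$theta_pi, d2$theta_pi, eps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out) <- sub("_1$", paste0("_", labs[1]), names(out))
  names(out) <- sub("_2$", paste0("_", labs[2]), names(out))
  attr(out, "pops") <- labs
  out
}
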