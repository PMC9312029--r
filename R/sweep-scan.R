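#' Empirical nearest-rank quantile threshold
#'
#' For the upper tail with fraction `f` over `N` finite values, returns the
#' value `v` such that at least `f * N` values are `>= v` and the count of
#' such values is minimal (the nearest-rank quantile, no interpolation);
#' symmetrically for the lower tail. Thresholds are therefore always attained
#' data values.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @param tail `"upper"` or `"lower"`.
#' @param fraction tail fraction in (0, 1).
#' @return The threshold value.
#' @export
empirical_threshold <- function(values, tail = c("upper", "lower"),
                                fraction = 0.05) {
  tail <- match.arg(tail)
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to take a quantile of")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (length(values) < 20)
    warning("fewer than 20 finite values; empirical threshold is unstable")
  k <- ceiling(fraction * length(values))
  sorted <- sort(values, decreasing = (tail == "upper"))
  sorted[k]
}

#' Sweep-selection criteria
#'
#' Joint outlier criteria for calling selective-sweep windows in a focal
#' population: high between-population Fst, reduced diversity in the focal
#' population, and (optionally) negative Tajima's D there.
#'
#' @param focal_population population label whose sweep windows are sought.
#' @param fst_quantile upper-tail fraction for the Fst clause. Default 0.05.
#' @param pi_quantile lower-tail fraction for the focal-population theta-pi
#'   clause. Default 0.10.
#' @param require_negative_d also require Tajima's D < 0 in the focal
#'   population. Default `TRUE`.
#' @param flank_bp flank added around merged sweep regions when collecting
#'   candidate genes. Default 20000.
#' @param cross_population if `TRUE`, the diversity clause compares the focal
#'   population's theta-pi against the *other* population's genome-wide
#'   distribution instead of its own (an alternative reading of the
#'   reduction-of-diversity rule). Default `FALSE`.
#' @return List of class `sweep_criteria`.
#' @export
sweep_criteria <- function(focal_population, fst_quantile = 0.05,
                           pi_quantile = 0.10, require_negative_d = TRUE,
                           flank_bp = 20000L, cross_population = FALSE) {
  stopifnot(fst_quantile > 0, fst_quantile < 1,
            pi_quantile > 0, pi_quantile < 1, flank_bp >= 0)
  structure(list(focal_population = focal_population,
                 fst_quantile = fst_quantile, pi_quantile = pi_quantile,
                 require_negative_d = require_negative_d,
                 flank_bp = as.integer(flank_bp),
                 cross_population = cross_population),
            class = "sweep_criteria")
}

#' Select sweep windows by joint empirical-quantile criteria
#'
#' A window is selected for the focal population iff its Fst is at or above
#' the upper `fst_quantile` threshold of the genome-wide Fst distribution,
#' its focal-population theta-pi is at or below the lower `pi_quantile`
#' threshold, and (if required) its focal-population Tajima's D is negative.
#' Which clauses fired is recorded per window.
#'
#' @param stats window table from [scan_windows()].
#' @param criteria a [sweep_criteria()].
#' @return `stats` with added logical columns `pass_fst`, `pass_pi`,
#'   `pass_d` and `selected`; thresholds in attributes `fst_threshold`,
#'   `pi_threshold`.
#' @export
select_sweep_windows <- function(stats, criteria) {
  if (!nrow(stats)) stop("empty window table")
  labs <- attr(stats, "pops")
  if (is.null(labs))
    stop("stats must come from scan_windows() (missing 'pops' attribute)")
  focal <- criteria$focal_population
  if (!focal %in% labs)
    stop("focal population '", focal, "' not in scan populations: ",
         paste(labs, collapse = ", "))
  other <- setdiff(labs, focal)
  pi_focal <- stats[[paste0("pi_", focal)]]
  d_focal <- stats[[paste0("tajd_", focal)]]
  fst_thr <- empirical_threshold(stats$fst, "upper", criteria$fst_quantile)
  pi_ref <- if (criteria$cross_population)
    stats[[paste0("pi_", other)]] else pi_focal
  pi_thr <- empirical_threshold(pi_ref, "lower", criteria$pi_quantile)
  pass_fst <- !is.na(stats$fst) & stats$fst >= fst_thr
  pass_pi <- !is.na(pi_focal) & pi_focal <= pi_thr
  pass_d <- if (criteria$require_negative_d)
    !is.na(d_focal) & d_focal < 0 else rep(TRUE, nrow(stats))
  stats$pass_fst <- pass_fst
  stats$pass_pi <- pass_pi
  stats$pass_d <- pass_d
  stats$selected <- pass_fst & pass_pi & pass_d
  attr(stats, "fst_threshold") <- fst_thr
  attr(stats, "pi_threshold") <- pi_thr
  attr(stats, "criteria") <- criteria
  attr(stats, "pops") <- labs
  stats
}

# genes as GRanges from a BED path / data.frame(chrom,start,end,gene_id) /
# GRanges. BED input is 0-based half-open; internal GRanges are 1-based
# closed.
genes_as_granges <- function(genes) {
  if (methods::is(genes, "GRanges")) return(genes)
  if (is.character(genes) && length(genes) == 1L) {
    gr <- rtracklayer::import(genes, format = "bed")
    if (is.null(gr$name)) gr$name <- paste0("gene", seq_along(gr))
    names(gr) <- gr$name
    return(gr)
  }
  if (is.data.frame(genes)) {
    id <- if ("gene_id" %in% names(genes)) genes$gene_id else
      if ("name" %in% names(genes)) genes$name else
        paste0("gene", seq_len(nrow(genes)))
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
    gr$name <- id
    names(gr) <- id
    return(gr)
  }
  stop("genes must be a BED path, a data.frame or a GRanges")
}

#' Merge selected windows into sweep regions and collect candidate genes
#'
#' Overlapping or abutting selected windows are merged into maximal regions;
#' a gene is a candidate for a region iff its span intersects the region
#' extended by `flank_bp` on both sides (half-open interval arithmetic, so a
#' gene starting exactly at the flank end is excluded).
#'
#' @param stats window table with a logical `selected` column (from
#'   [select_sweep_windows()]), or any data.frame of windows with `chrom`,
#'   `start`, `end` -- all rows are then taken as selected.
#' @param genes gene spans: BED path, data.frame (`chrom`, `start`, `end`,
#'   `gene_id`; 0-based half-open) or `GRanges`. `NULL` for no annotation.
#' @param flank_bp candidate-gene flank in bp. Default 20000.
#' @return data.frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open), `n_windows`, `n_genes`, `genes` (comma-separated ids);
#'   the per-region member-window indices are kept in the
#'   `"member_windows"` attribute.
#' @export
merge_and_annotate <- function(stats, genes = NULL, flank_bp = 20000L) {
  sel <- if ("selected" %in% names(stats)) stats[stats$selected, , drop = FALSE]
  else stats
  if (!nrow(sel))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      n_genes = integer(0), genes = character(0),
                      stringsAsFactors = FALSE))
  wgr <- GenomicRanges::GRanges(sel$chrom,
                                IRanges::IRanges(sel$start + 1L, sel$end))
  red <- GenomicRanges::reduce(wgr, min.gapwidth = 1L)
  memb <- GenomicRanges::findOverlaps(red, wgr)
  regions <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                        start = GenomicRanges::start(red) - 1L,
                        end = GenomicRanges::end(red),
                        n_windows = tabulate(S4Vectors::queryHits(memb),
                                             length(red)),
                        stringsAsFactors = FALSE)
  gene_lists <- vector("list", nrow(regions))
  if (!is.null(genes)) {
    ggr <- genes_as_granges(genes)
    ext <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(pmax(1L, regions$start - flank_bp + 1L),
                       regions$end + flank_bp))
    hits <- GenomicRanges::findOverlaps(ext, ggr)
    for (i in seq_len(nrow(regions))) {
      g <- ggr$name[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
      gene_lists[[i]] <- sort(unique(g))
    }
  } else gene_lists <- replicate(nrow(regions), character(0), simplify = FALSE)
  regions$n_genes <- lengths(gene_lists)
  regions$genes <- vapply(gene_lists, paste, character(1), collapse = ",")
  attr(regions, "member_windows") <-
    split(S4Vectors::subjectHits(memb), S4Vectors::queryHits(memb))
  attr(regions, "gene_lists") <- gene_lists
  regions
}

#' All candidate genes across sweep regions
#'
#' @param regions output of [merge_and_annotate()].
#' @return Sorted unique character vector of candidate gene ids.
#' @export
candidate_genes <- function(regions) {
  sort(unique(unlist(attr(regions, "gene_lists"))))
}
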