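#' Copy-number matrix
#'
#' Real-valued copy numbers for genomic regions (rows) by samples (columns),
#' with a two-population sample assignment -- the substrate of the Vst scan.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param CN numeric matrix, regions x samples, entries `>= 0`.
#' @param pops named character vector sample -> population label.
#' @return Object of class `cn_matrix`.
#' @export
cn_matrix <- function(regions, CN, pops) {
  CN <- as.matrix(CN)
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)),
            nrow(CN) == nrow(regions))
  if (any(CN < 0, na.rm = TRUE)) stop("copy numbers must be >= 0")
  samples <- colnames(CN)
  if (is.null(samples)) stop("CN needs sample column names")
  pops <- pops[samples]
  if (anyNA(pops)) stop("every sample needs a population label")
  if (length(unique(pops)) != 2L) stop("exactly two populations required")
  structure(list(regions = regions, CN = CN, samples = samples, pops = pops),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d regions x %d samples (%s)\n", nrow(x$CN),
              ncol(x$CN), paste(names(table(x$pops)), collapse = " vs ")))
  invisible(x)
}

#' Read a copy-number TSV
#'
#' Expected format: columns `chrom`, `start`, `end` (0-based half-open)
#' followed by one numeric column per sample.
#'
#' @param path TSV path.
#' @param pop_map sample-to-population map (named vector, data.frame or TSV
#'   path, as in [read_vcf()]).
#' @return A [cn_matrix()].
#' @export
read_cnv_matrix <- function(path, pop_map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  pops <- read_pop_map(pop_map)
  samples <- setdiff(names(tab), c("chrom", "start", "end"))
  cn_matrix(tab[c("chrom", "start", "end")],
            as.matrix(tab[samples]), pops)
}

#' Vst: between-population differentiation of copy number
#'
#' `Vst = (V_T - V_S) / V_T` where `V_T` is the total variance of the copy
#' numbers and `V_S` the sample-size-weighted mean of the within-population
#' variances; all variances use denominator `n` (population variances), so
#' two internally constant but different populations give exactly 1.
#' Numerically negative values are clamped to 0; `NA` when `V_T = 0`.
#'
#' @param cn numeric vector of copy numbers for one region.
#' @param pops population label per entry (exactly two levels, both
#'   non-empty).
#' @return List with `vst`, `v_total`, `v_within`.
#' @export
vst <- function(cn, pops) {
  if (length(cn) < 2) stop("need at least two samples")
  if (length(pops) != length(cn)) stop("pops must match cn in length")
  labs <- sort(unique(pops))
  if (length(labs) != 2L)
    stop("exactly two non-empty populations required, got: ",
         paste(labs, collapse = ", "))
  popvar <- function(x) mean((x - mean(x))^2)
  v_t <- popvar(cn)
  x1 <- cn[pops == labs[1]]
  x2 <- cn[pops == labs[2]]
  v_s <- (popvar(x1) * length(x1) + popvar(x2) * length(x2)) / length(cn)
  if (v_t == 0) return(list(vst = NA_real_, v_total = 0, v_within = v_s))
  list(vst = max(0, (v_t - v_s) / v_t), v_total = v_t, v_within = v_s)
}

#' Vst scan with empirical-quantile outlier extraction
#'
#' Computes Vst for every region of a copy-number matrix, takes the upper
#' `fraction` nearest-rank threshold of the defined Vst values, reports the
#' selected regions with overlapping genes, and summarises them (count,
#' total length, mean length).
#'
#' @param cnm a [cn_matrix()].
#' @param fraction upper-tail fraction. Default 0.05 (`1` selects every
#'   region with a defined Vst).
#' @param genes optional gene spans (BED path / data.frame / GRanges) for
#'   overlap annotation (no flank).
#' @return List with `table` (regions + `vst`, `v_total`, `v_within`,
#'   `selected`, `genes`), `threshold`, `selected` (subset of `table`) and
#'   `summary` (`n_selected`, `total_bp`, `mean_length_bp`, `n_genes`).
#' @export
vst_scan <- function(cnm, fraction = 0.05, genes = NULL) {
  if (!nrow(cnm$CN)) stop("empty copy-number matrix")
  vs <- lapply(seq_len(nrow(cnm$CN)), function(i)
    vst(cnm$CN[i, ], cnm$pops))
  tab <- cnm$regions
  tab$vst <- vapply(vs, `[[`, numeric(1), "vst")
  tab$v_total <- vapply(vs, `[[`, numeric(1), "v_total")
  tab$v_within <- vapply(vs, `[[`, numeric(1), "v_within")
  thr <- if (fraction >= 1) 0 else
    empirical_threshold(tab$vst, "upper", fraction)
  tab$selected <- !is.na(tab$vst) & tab$vst >= thr
  gene_col <- rep("", nrow(tab))
  if (!is.null(genes)) {
    ggr <- genes_as_granges(genes)
    rgr <- GenomicRanges::GRanges(tab$chrom,
                                  IRanges::IRanges(tab$start + 1L, tab$end))
    hits <- GenomicRanges::findOverlaps(rgr, ggr)
    for (i in unique(S4Vectors::queryHits(hits))) {
      g <- ggr$name[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
      gene_col[i] <- paste(sort(unique(g)), collapse = ",")
    }
  }
  tab$genes <- gene_col
  sel <- tab[tab$selected, , drop = FALSE]
  sel_genes <- sort(unique(unlist(strsplit(sel$genes[nzchar(sel$genes)], ","))))
  list(table = tab, threshold = thr, selected = sel,
       genes = sel_genes,
       summary = list(n_selected = nrow(sel),
                      total_bp = sum(sel$end - sel$start),
                      mean_length_bp = if (nrow(sel))
                        mean(sel$end - sel$start) else NA_real_,
                      n_genes = length(sel_genes)))
}
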