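#' Upper-tail hypergeometric p-value
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)` (a candidate set of size
#' `n` drawn from a universe of `N` genes of which `K` carry the term),
#' accumulated from log-scale probability masses for numerical stability.
#'
#' @param x observed number of candidates carrying the term.
#' @param K genes carrying the term in the background.
#' @param n candidate-set size.
#' @param N background-universe size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_upper_p <- function(x, K, n, N) {
  if (any(c(x, K, n, N) < 0) || K > N || n > N || x > min(K, n))
    stop("inconsistent hypergeometric counts (need 0 <= x <= min(K, n) <= N)")
  if (x == 0) return(1)
  i <- seq(x, min(K, n))
  min(1, sum(exp(stats::dhyper(i, K, N - K, n, log = TRUE))))
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni adjustment of a
#' p-value vector, capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}

# annotations as a named list term -> character vector of genes, from a
# two-column data.frame (gene, term), a TSV path, or a list as-is
as_term_list <- function(annotations) {
  if (is.list(annotations) && !is.data.frame(annotations)) return(annotations)
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- utils::read.table(annotations, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
  if (is.data.frame(annotations)) {
    gene <- annotations[[1]]
    term <- annotations[[2]]
    return(split(as.character(gene), as.character(term)))
  }
  stop("annotations must be a term list, data.frame or TSV path")
}

#' Term over-representation test
#'
#' One upper-tail hypergeometric test per term with at least one annotated
#' background gene, with multiple-testing correction. By default the
#' background universe is the set of all annotated genes.
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of the background).
#' @param annotations gene-to-term annotation: named list (term -> genes),
#'   two-column data.frame (`gene`, `term`) or TSV path.
#' @param background character vector of background gene ids; default all
#'   genes in `annotations`.
#' @param alpha significance level on the adjusted p-value. Default 0.05.
#' @param method correction method, `"BH"` (default) or `"bonferroni"`.
#' @return data.frame sorted by p-value: `term`, `x`, `K`, `n`, `N`, `p`,
#'   `q`, `significant`.
#' @export
enrich <- function(candidates, annotations, background = NULL, alpha = 0.05,
                   method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  terms <- as_term_list(annotations)
  if (is.null(background)) background <- unique(unlist(terms))
  background <- unique(as.character(background))
  candidates <- unique(as.character(candidates))
  outside <- setdiff(candidates, background)
  if (length(outside))
    stop("candidate gene(s) outside the background universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  N <- length(background)
  n <- length(candidates)
  rows <- lapply(names(terms), function(tm) {
    genes <- intersect(unique(terms[[tm]]), background)
    K <- length(genes)
    if (K < 1) return(NULL)
    x <- length(intersect(genes, candidates))
    data.frame(term = tm, x = x, K = K, n = n, N = N,
               p = hypergeom_upper_p(x, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), x = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  out$q <- adjust_pvalues(out$p, method)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$q < alpha
  out
}
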