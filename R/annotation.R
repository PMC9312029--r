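#' Gene model
#'
#' Minimal transcript model for region and coding-effect classification:
#' sorted non-overlapping exons, CDS intervals contained in exons, strand.
#' All intervals are 1-based closed (GFF convention).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of exon (start, end).
#' @param cds optional two-column matrix of CDS (start, end); `NULL` for a
#'   non-coding model.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("exons must be sorted and non-overlapping")
  if (any(exons[, 2] < exons[, 1])) stop("exon end before start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(cds)) {
    cds <- as.matrix(cds)[, 1:2, drop = FALSE]
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    inside <- vapply(seq_len(nrow(cds)), function(i)
      any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2]), logical(1))
    if (!all(inside)) stop("CDS intervals must lie inside exons")
  }
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 strand = strand, exons = unname(exons), cds = unname(cds),
                 tx_start = min(exons[, 1]), tx_end = max(exons[, 2])),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Groups `exon` and `CDS` features by their parent/gene attribute into
#' [gene_model()] objects (parsing via rtracklayer).
#'
#' @param path GFF3 path.
#' @return Named list of `gene_model`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  get_id <- function(i) {
    for (key in c("Parent", "gene_id", "ID", "Name")) {
      if (key %in% names(md)) {
        v <- md[[key]][i]
        if (is(v, "List") || is.list(v)) v <- unlist(v)
        if (length(v) && !is.na(v[1]) && nzchar(v[1])) return(as.character(v[1]))
      }
    }
    NA_character_
  }
  type <- as.character(md$type)
  feat_idx <- which(type %in% c("exon", "CDS"))
  ids <- vapply(feat_idx, get_id, character(1))
  out <- list()
  for (gid in unique(ids)) {
    sel <- feat_idx[ids == gid]
    sub <- gr[sel]
    ex <- sub[type[sel] == "exon"]
    cd <- sub[type[sel] == "CDS"]
    exons <- if (length(ex)) cbind(GenomicRanges::start(ex),
                                   GenomicRanges::end(ex))
    else cbind(GenomicRanges::start(cd), GenomicRanges::end(cd))
    cds <- if (length(cd)) cbind(GenomicRanges::start(cd),
                                 GenomicRanges::end(cd)) else NULL
    out[[gid]] <- gene_model(gid,
                             as.character(GenomicRanges::seqnames(sub))[1],
                             as.character(GenomicRanges::strand(sub))[1],
                             exons, cds)
  }
  out
}

# splice window: first/last two intron bases
SPLICE_BP <- 2L

# region of a position within one gene model
region_in_gene <- function(pos, model) {
  ex <- model$exons
  in_exon <- which(pos >= ex[, 1] & pos <= ex[, 2])
  if (length(in_exon)) {
    if (!is.null(model$cds)) {
      if (any(pos >= model$cds[, 1] & pos <= model$cds[, 2])) return("CDS")
      cds_lo <- min(model$cds[, 1]); cds_hi <- max(model$cds[, 2])
      upstream <- pos < cds_lo
      if (model$strand == "+") return(if (upstream) "UTR5" else "UTR3")
      return(if (pos > cds_hi) "UTR5" else "UTR3")
    }
    return("UTR5")  # non-coding model: exonic, reported as untranslated
  }
  # intron: exon gaps
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      lo <- ex[i, 2] + 1L; hi <- ex[i + 1, 1] - 1L
      if (pos >= lo && pos <= hi) {
        if (pos <= lo + SPLICE_BP - 1L || pos >= hi - SPLICE_BP + 1L)
          return("splice")
        return("intronic")
      }
    }
  }
  "intergenic"
}

#' Assign a genomic region to each variant
#'
#' Classifies positions as intergenic / UTR5 / UTR3 / CDS / splice /
#' intronic against a set of gene models. Splice = the first or last two
#' bases of an intron; CDS takes precedence over UTR and splice over plain
#' intron. A variant overlapping several genes is classified against the
#' first by (gene start, gene_id) order and the multiplicity is recorded.
#' Chromosomes absent from the models are intergenic with a warning.
#'
#' @param chrom,pos vectors of variant coordinates (1-based).
#' @param models list of [gene_model()] (e.g. from [read_gene_models()]).
#' @return data.frame with `chrom`, `pos`, `region`, `gene_id` (`NA`
#'   outside genes) and `n_genes` (overlapping gene count).
#' @export
assign_region <- function(chrom, pos, models) {
  model_chroms <- vapply(models, `[[`, character(1), "chrom")
  starts <- vapply(models, `[[`, numeric(1), "tx_start")
  ids <- vapply(models, `[[`, character(1), "gene_id")
  ord <- order(starts, ids)
  models <- models[ord]; model_chroms <- model_chroms[ord]
  missing_chrom <- setdiff(unique(chrom), unique(model_chroms))
  if (length(missing_chrom))
    warning("no gene models on chromosome(s) ",
            paste(missing_chrom, collapse = ", "),
            "; variants there classified intergenic")
  n <- length(pos)
  region <- character(n); gene <- rep(NA_character_, n)
  n_genes <- integer(n)
  for (v in seq_len(n)) {
    hit <- which(model_chroms == chrom[v] &
                   vapply(models, function(m)
                     pos[v] >= m$tx_start && pos[v] <= m$tx_end, logical(1)))
    n_genes[v] <- length(hit)
    if (!length(hit)) { region[v] <- "intergenic"; next }
    m <- models[[hit[1]]]
    region[v] <- region_in_gene(pos[v], m)
    if (region[v] != "intergenic") gene[v] <- m$gene_id
  }
  data.frame(chrom = chrom, pos = pos, region = region, gene_id = gene,
             n_genes = n_genes, stringsAsFactors = FALSE)
}

# reverse complement of a character DNA string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Classify the coding effect of a SNP inside a CDS
#'
#' Rebuilds the affected codon from the reference sequence honoring strand
#' and reading frame, substitutes the alternate base, and compares the two
#' amino acids under the standard genetic code.
#'
#' @param pos 1-based variant position (must lie in the model's CDS).
#' @param ref,alt single reference / alternate bases (plus-strand, as in the
#'   VCF).
#' @param model a coding [gene_model()].
#' @param ref_seq chromosome sequence: a `Biostrings::DNAString` or a plain
#'   character string.
#' @return List with `effect` (`"synonymous"`, `"nonsynonymous"`,
#'   `"stopgain"`, `"stoploss"`), `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `codon_index`.
#' @export
classify_coding_effect <- function(pos, ref, alt, model, ref_seq) {
  if (is.null(model$cds)) stop("model has no CDS")
  if (!is(ref_seq, "DNAString")) ref_seq <- Biostrings::DNAString(ref_seq)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("coding-effect classification is defined for single-base SNPs")
  in_cds <- which(pos >= model$cds[, 1] & pos <= model$cds[, 2])
  if (!length(in_cds)) stop("position is not inside the model's CDS")
  genome_base <- as.character(ref_seq[pos])
  if (genome_base != toupper(ref))
    stop("reference mismatch at ", model$chrom, ":", pos, " (genome ",
         genome_base, ", variant ref ", ref, ")")
  cds_seq <- paste(vapply(seq_len(nrow(model$cds)), function(i)
    as.character(ref_seq[model$cds[i, 1]:model$cds[i, 2]]), character(1)),
    collapse = "")
  # plus-strand offset of pos within the concatenated CDS
  off <- 0L
  for (i in seq_len(nrow(model$cds))) {
    if (i < in_cds[1]) off <- off + (model$cds[i, 2] - model$cds[i, 1] + 1L)
  }
  plus_idx <- off + (pos - model$cds[in_cds[1], 1]) + 1L
  if (model$strand == "-") {
    cds_seq <- revcomp(cds_seq)
    cds_idx <- nchar(cds_seq) - plus_idx + 1L
    alt_base <- revcomp(toupper(alt))
  } else {
    cds_idx <- plus_idx
    alt_base <- toupper(alt)
  }
  codon_i <- (cds_idx - 1L) %/% 3L
  codon_start <- codon_i * 3L + 1L
  ref_codon <- substr(cds_seq, codon_start, codon_start + 2L)
  within <- cds_idx - codon_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  effect <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*" && ref_aa != "*") "stopgain"
  else if (ref_aa == "*" && alt_aa != "*") "stoploss"
  else "nonsynonymous"
  list(effect = effect, ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, codon_index = codon_i + 1L)
}

#' Summarise variant-effect calls
#'
#' Counts region and coding-effect categories, the
#' nonsynonymous-to-synonymous ratio (`NA` when no synonymous call), and an
#' optional InDel length spectrum (1--200 bp bins, share of 1--6 bp events
#' and of in-frame 3n-length events).
#'
#' @param regions character vector of region labels (as produced by
#'   [assign_region()]).
#' @param effects optional character vector of coding-effect labels for the
#'   CDS variants.
#' @param indel_lengths optional integer vector of InDel lengths (bp).
#' @return List with `region_counts`, `effect_counts`, `nonsyn_syn_ratio`,
#'   and (when lengths are given) `indel_hist`, `share_1_6bp`,
#'   `share_inframe`.
#' @export
effect_summary <- function(regions, effects = NULL, indel_lengths = NULL) {
  region_levels <- c("intergenic", "intronic", "UTR5", "UTR3", "CDS",
                     "splice")
  region_counts <- table(factor(regions, levels = region_levels))
  effect_levels <- c("synonymous", "nonsynonymous", "stopgain", "stoploss")
  effect_counts <- table(factor(effects, levels = effect_levels))
  ns <- unname(effect_counts["nonsynonymous"])
  s <- unname(effect_counts["synonymous"])
  out <- list(region_counts = region_counts, effect_counts = effect_counts,
              nonsyn_syn_ratio = if (!is.null(effects) && s > 0) ns / s
              else NA_real_)
  if (!is.null(indel_lengths)) {
    len <- abs(as.integer(indel_lengths))
    len <- len[len >= 1]
    out$indel_hist <- table(factor(pmin(len, 200L), levels = 1:200))
    out$share_1_6bp <- if (length(len)) mean(len <= 6) else NA_real_
    out$share_inframe <- if (length(len)) mean(len %% 3 == 0) else NA_real_
  }
  out
}
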