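#' Variant record set
#'
#' Container for the per-record fields the filters and annotators need:
#' a site table (chrom, 1-based pos, ref, alt, qual, total depth), a genotype
#' call matrix (VCF-style strings, sites x samples) and a per-sample
#' supporting-read matrix.
#'
#' @param site data.frame with columns `chrom`, `pos`, `ref`, `alt` (comma
#'   separated for multi-allelic sites), `qual`, `depth`.
#' @param gt character matrix of genotype calls (`"0/1"`, `NA` for missing),
#'   sites in rows, samples in columns.
#' @param sr numeric matrix of per-sample supporting reads, same shape as
#'   `gt` (may be all `NA` when the source VCF lacks per-sample depth).
#' @param samples character vector of sample ids (defaults to
#'   `colnames(gt)`).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(site, gt, sr = NULL, samples = colnames(gt)) {
  stopifnot(is.data.frame(site),
            all(c("chrom", "pos", "ref", "alt", "qual", "depth") %in%
                  names(site)))
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(site)) stop("gt must have one row per site")
  if (is.null(sr)) sr <- matrix(NA_real_, nrow(gt), ncol(gt))
  sr <- as.matrix(sr)
  if (!all(dim(sr) == dim(gt))) stop("sr must have the same shape as gt")
  if (any(site$pos < 1)) stop("positions must be >= 1 (VCF convention)")
  if (any(!nzchar(site$ref))) stop("ref alleles must be non-empty")
  colnames(gt) <- samples
  colnames(sr) <- samples
  rownames(site) <- NULL
  structure(list(site = site, gt = gt, sr = sr, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d records, %d samples, %d chromosome(s)\n",
              nrow(x$site), length(x$samples), length(unique(x$site$chrom))))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$site)

#' Subset a variant set by record index
#' @param x a [variant_set()].
#' @param i integer or logical index over records.
#' @param ... unused.
#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$site[i, , drop = FALSE], x$gt[i, , drop = FALSE],
              x$sr[i, , drop = FALSE], samples = x$samples)
}

# dosage of one genotype-string vector under a biallelic model:
# number of "1" alleles; any allele index > 1 or missing call -> NA
gt_to_dosage <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  alleles <- strsplit(gsub("\\|", "/", gt[ok]), "/", fixed = TRUE)
  out[ok] <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai > 1L)) return(NA_integer_)
    sum(ai)
  }, integer(1))
  out
}

# sites x samples dosage matrix for biallelic records
dosage_matrix <- function(vs) {
  apply(vs$gt, 2L, gt_to_dosage)
}

read_pop_map <- function(pop_map) {
  if (is.null(pop_map)) return(NULL)
  if (is.character(pop_map) && length(pop_map) == 1L && file.exists(pop_map)) {
    tab <- utils::read.table(pop_map, header = FALSE, sep = "\t",
                             col.names = c("sample", "population"),
                             colClasses = "character")
    pop_map <- stats::setNames(tab$population, tab$sample)
  } else if (is.data.frame(pop_map)) {
    pop_map <- stats::setNames(as.character(pop_map[[2]]),
                               as.character(pop_map[[1]]))
  }
  pop_map
}

#' Read a multi-sample VCF into variant records and genotype matrices
#'
#' Parses a VCF 4.x file (via the vcfR package), returning the raw variant
#' records plus one biallelic [geno_matrix()] per chromosome. Multi-allelic
#' sites are kept in the record set, flagged, and excluded from the genotype
#' matrices (every downstream statistic assumes two alleles).
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param pop_map sample-to-population assignment: a named character vector,
#'   a two-column data.frame (sample, population), or the path to a
#'   two-column TSV. Every sample in the VCF header must be present.
#' @return List with `records` (a [variant_set()] with a `multiallelic`
#'   column in its site table), `matrices` (named list of `geno_matrix`, one
#'   per chromosome, biallelic sites only) and `pops`.
#' @export
read_vcf <- function(path, pop_map = NULL) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  pop_map <- read_pop_map(pop_map)
  if (!is.null(pop_map)) {
    missing_from_map <- setdiff(samples, names(pop_map))
    if (length(missing_from_map))
      stop("sample(s) in VCF but not in pop_map: ",
           paste(missing_from_map, collapse = ", "))
    missing_from_vcf <- setdiff(names(pop_map), samples)
    if (length(missing_from_vcf))
      stop("sample(s) in pop_map but not in VCF header: ",
           paste(missing_from_vcf, collapse = ", "))
    pop_map <- pop_map[samples]
  }
  pos <- as.integer(fix[, "POS"])
  if (anyNA(pos))
    stop("malformed VCF: non-numeric POS at data line ",
         paste(which(is.na(pos)), collapse = ", "))
  info <- fix[, "INFO"]
  depth <- suppressWarnings(as.integer(sub(".*\\bDP=([0-9]+).*", "\\1",
                                           ifelse(grepl("\\bDP=", info), info, NA))))
  site <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                     depth = depth, stringsAsFactors = FALSE)
  site$multiallelic <- grepl(",", site$alt, fixed = TRUE)
  if (n_rec > 0) {
    gt <- vcfR::extract.gt(v, element = "GT")
    sr <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                            as.numeric = TRUE))
    if (is.null(sr)) sr <- matrix(NA_real_, n_rec, length(samples))
    if (is.null(dim(gt))) {
      gt <- matrix(gt, nrow = n_rec)
      sr <- matrix(sr, nrow = n_rec)
    }
    colnames(gt) <- samples
  } else {
    gt <- matrix(character(0), 0, length(samples),
                 dimnames = list(NULL, samples))
    sr <- matrix(numeric(0), 0, length(samples))
  }
  records <- variant_set(site, gt, sr, samples = samples)
  list(records = records,
       matrices = genotype_matrices(records, pop_map),
       pops = pop_map)
}

#' Build per-chromosome genotype matrices from variant records
#'
#' @param vs a [variant_set()].
#' @param pops optional named character vector sample -> population.
#' @return Named list of [geno_matrix()], one per chromosome, restricted to
#'   biallelic records; missing genotypes preserved as `NA`.
#' @export
genotype_matrices <- function(vs, pops = NULL) {
  pops <- read_pop_map(pops)
  bi <- !grepl(",", vs$site$alt, fixed = TRUE)
  out <- list()
  for (chr in unique(vs$site$chrom)) {
    idx <- which(vs$site$chrom == chr & bi)
    if (!length(idx)) next
    D <- t(dosage_matrix(vs[idx]))  # samples x sites
    rownames(D) <- vs$samples
    out[[chr]] <- geno_matrix(D, vs$site$pos[idx], chr, samples = vs$samples,
                              pops = pops, ref = vs$site$ref[idx],
                              alt = vs$site$alt[idx])
  }
  out
}

#' Write variant records as VCF 4.2
#'
#' Emits a plain-text VCF whose fields round-trip through [read_vcf()]
#' (genotypes as `GT:DP` with per-sample supporting reads, total depth as
#' `INFO/DP`).
#'
#' @param vs a [variant_set()], records sorted by (chrom, pos).
#' @param path output path.
#' @param contigs optional named integer vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, contigs = NULL) {
  site <- vs$site
  if (nrow(site) > 1) {
    o <- order(match(site$chrom, unique(site$chrom)), site$pos)
    if (!identical(o, seq_len(nrow(site))))
      stop("records must be sorted by (chrom, pos)")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popgenscan",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  lines <- character(nrow(site))
  if (nrow(site)) {
    gt <- vs$gt
    gt[is.na(gt)] <- "./."
    srf <- matrix(fmt_num(vs$sr), nrow(site))
    cells <- matrix(paste(gt, srf, sep = ":"), nrow(site))
    sample_field <- apply(cells, 1L, paste, collapse = "\t")
    lines <- paste(site$chrom, site$pos, ".", site$ref, site$alt,
                   fmt_num(site$qual), ".",
                   ifelse(is.na(site$depth), ".",
                          paste0("DP=", fmt_num(site$depth))),
                   "GT:DP", sample_field, sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

#' Variant filter configuration
#'
#' The per-record quality rules and the inter-SNP spacing rule. Thresholds
#' are strict inequalities: a record survives only with
#' `qual > min_qual`, minimum per-sample supporting reads
#' `> min_supporting_reads`, total depth `< max_depth` and
#' `MAF > min_maf`; surviving SNPs on a chromosome must then be at least
#' `min_spacing_bp` apart (the earlier record wins a conflict).
#'
#' Three optional rules mirror upstream calling-stage criteria and read
#' pre-computed INFO-style columns when present: `max_copy_number` (flanking
#' copy number, site column `cn`), `cohort_depth_range` (two-sided bound on
#' cohort sequencing depth, column `cohort_dp`) and `min_ranksum_p` (rank-sum
#' test p-value, column `ranksum_p`). Each is skipped with a warning when its
#' column is absent.
#'
#' @param min_qual minimum phred quality (exclusive). Default 20.
#' @param min_supporting_reads minimum per-sample supporting reads
#'   (exclusive). Default 4.
#' @param max_depth maximum total depth (exclusive). Default 100.
#' @param min_maf minimum minor allele frequency (exclusive). Default 0.05.
#' @param min_spacing_bp minimum distance between surviving SNPs. Default 5.
#' @param biallelic_only drop multi-allelic records. Default `TRUE`.
#' @param max_copy_number,cohort_depth_range,min_ranksum_p optional rules
#'   (default `NULL` = disabled).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 20, min_supporting_reads = 4,
                          max_depth = 100, min_maf = 0.05,
                          min_spacing_bp = 5, biallelic_only = TRUE,
                          max_copy_number = NULL, cohort_depth_range = NULL,
                          min_ranksum_p = NULL) {
  stopifnot(min_qual >= 0, min_supporting_reads >= 0, max_depth >= 0,
            min_maf >= 0, min_maf <= 0.5, min_spacing_bp >= 0)
  structure(list(min_qual = min_qual,
                 min_supporting_reads = min_supporting_reads,
                 max_depth = max_depth, min_maf = min_maf,
                 min_spacing_bp = min_spacing_bp,
                 biallelic_only = biallelic_only,
                 max_copy_number = max_copy_number,
                 cohort_depth_range = cohort_depth_range,
                 min_ranksum_p = min_ranksum_p),
            class = "filter_config")
}

#' Filter variant records
#'
#' Applies the per-record rules of [filter_config()] in a fixed order
#' (quality, biallelic, supporting reads, depth, MAF, optional rules), then
#' the left-to-right spacing rule on the survivors. Each rejected record is
#' attributed to the first rule it fails, so the rejection counts plus the
#' survivor count always equal the input count.
#'
#' @param vs a [variant_set()], sorted by (chrom, pos).
#' @param cfg a [filter_config()].
#' @return List with `records` (surviving [variant_set()]), `kept` (logical
#'   over input records), `counts` (named rejection counts + `survivors`)
#'   and `reason` (per-record character, `"kept"` for survivors).
#' @export
filter_variants <- function(vs, cfg = filter_config()) {
  site <- vs$site
  n <- nrow(site)
  o <- order(match(site$chrom, unique(site$chrom)), site$pos)
  if (!identical(o, seq_len(max(n, 1L))) && n > 1)
    stop("records must be sorted by (chrom, pos) before filtering")
  reason <- rep(NA_character_, n)
  fail <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    hit <- cond & is.na(reason)
    reason[hit] <<- label
  }
  fail(is.na(site$qual) | site$qual <= cfg$min_qual, "qual")
  if (isTRUE(cfg$biallelic_only))
    fail(grepl(",", site$alt, fixed = TRUE), "multiallelic")
  # minimum supporting reads across genotyped samples; records with no
  # per-sample depth at all pass this rule
  min_sr <- rep(NA_real_, n)
  if (n) {
    called <- !is.na(vs$gt)
    srm <- vs$sr
    srm[!called] <- NA_real_
    has <- rowSums(!is.na(srm)) > 0
    min_sr[has] <- apply(srm[has, , drop = FALSE], 1L, min, na.rm = TRUE)
  }
  fail(!is.na(min_sr) & min_sr <= cfg$min_supporting_reads, "supporting_reads")
  fail(!is.na(site$depth) & site$depth >= cfg$max_depth, "depth")
  maf <- rep(NA_real_, n)
  if (n) {
    D <- dosage_matrix(vs)
    if (is.null(dim(D))) D <- matrix(D, nrow = n)
    sc <- site_counts(t(D))
    maf <- ifelse(sc$n > 0, pmin(sc$alt / sc$n, 1 - sc$alt / sc$n), NA_real_)
  }
  fail(is.na(maf) | maf <= cfg$min_maf, "maf")
  opt_rule <- function(col, cond_fn, label) {
    if (is.null(cfg[[label]])) return()
    if (!col %in% names(site)) {
      warning("optional filter '", label, "' requested but column '", col,
              "' is absent; rule skipped")
      return()
    }
    fail(cond_fn(site[[col]]), label)
  }
  opt_rule("cn", function(x) !is.na(x) & x >= cfg$max_copy_number,
           "max_copy_number")
  opt_rule("cohort_dp", function(x)
    !is.na(x) & (x <= cfg$cohort_depth_range[1] |
                   x >= cfg$cohort_depth_range[2]), "cohort_depth_range")
  opt_rule("ranksum_p", function(x) !is.na(x) & x <= cfg$min_ranksum_p,
           "min_ranksum_p")
  # spacing: scan survivors left to right per chromosome, keep the earlier
  # record of a too-close pair
  if (cfg$min_spacing_bp > 0 && n) {
    for (chr in unique(site$chrom)) {
      idx <- which(site$chrom == chr & is.na(reason))
      last_kept <- -Inf
      for (i in idx) {
        if (site$pos[i] - last_kept < cfg$min_spacing_bp) {
          reason[i] <- "spacing"
        } else last_kept <- site$pos[i]
      }
    }
  }
  kept <- is.na(reason)
  reason[kept] <- "kept"
  rules <- c("qual", "multiallelic", "supporting_reads", "depth", "maf",
             "max_copy_number", "cohort_depth_range", "min_ranksum_p",
             "spacing")
  counts <- vapply(rules, function(r) sum(reason == r), integer(1))
  counts <- c(counts, survivors = sum(kept))
  list(records = vs[kept], kept = kept, counts = counts, reason = reason)
}
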