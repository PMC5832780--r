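#' Build LD blocks around index disease SNPs from a proxy table
#'
#' The LD block of an index SNP spans the index position and every proxy
#' with `r^2 >= r2_min` (default 0.9); an index with no qualifying proxy
#' gets a 1-bp block at its own position.  Raising `r2_min` can only
#' shrink blocks.
#'
#' @param proxies `data.frame` with columns `index_rsid`, `proxy_rsid`,
#'   `pos` (0-based), `r2`.
#' @param snps Disease-SNP catalog: `data.frame` with `rsid`, `chrom`,
#'   `pos` (0-based), and optionally `maf`, `phenotype`.
#' @param r2_min Minimum r-squared for block membership.
#' @return `data.frame`, one row per index SNP present in `snps`:
#'   `index_rsid`, `chrom`, `start`, `end` (0-based half-open),
#'   `n_proxies`.
#' @export
build_ld_blocks <- function(proxies, snps, r2_min = 0.9) {
  stopifnot(all(c("rsid", "chrom", "pos") %in% names(snps)))
  idx <- unique(proxies$index_rsid)
  missing <- setdiff(idx, snps$rsid)
  if (length(missing))
    stop("index rsid(s) absent from SNP catalog: ",
         paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    rsid <- snps$rsid[i]
    p <- proxies[proxies$index_rsid == rsid & proxies$r2 >= r2_min, ,
                 drop = FALSE]
    pos <- c(snps$pos[i], p$pos)
    data.frame(index_rsid = rsid, chrom = snps$chrom[i],
               start = min(pos), end = max(pos) + 1L,
               n_proxies = nrow(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intersect miRNA loci with disease-SNP LD blocks
#'
#' One association row per (miRNA locus, LD block) pair sharing at least
#' one base, strand-blind.
#'
#' @param mirna_loci Interval `data.frame` with a `name` column.
#' @param blocks LD blocks from [build_ld_blocks()].
#' @return `data.frame` with `mirna`, `index_rsid`, `chrom`,
#'   `overlap_start`, `overlap_end`.
#' @export
intersect_mirna_ld <- function(mirna_loci, blocks) {
  empty <- data.frame(mirna = character(0), index_rsid = character(0),
                      chrom = character(0), overlap_start = integer(0),
                      overlap_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(mirna_loci) == 0L || nrow(blocks) == 0L) return(empty)
  bgr <- as_granges(data.frame(chrom = blocks$chrom, start = blocks$start,
                               end = blocks$end))
  mgr <- as_granges(mirna_loci[, c("chrom", "start", "end")])
  ov <- GenomicRanges::findOverlaps(mgr, bgr, ignore.strand = TRUE)
  if (length(ov) == 0L) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  data.frame(mirna = mirna_loci$name[qi],
             index_rsid = blocks$index_rsid[si],
             chrom = mirna_loci$chrom[qi],
             overlap_start = pmax(mirna_loci$start[qi], blocks$start[si]),
             overlap_end = pmin(mirna_loci$end[qi], blocks$end[si]),
             stringsAsFactors = FALSE)
}

# split a phenotype field on ';' and normalize labels for deduplication
normalize_phenotypes <- function(x) {
  labs <- unlist(strsplit(as.character(x), ";", fixed = TRUE))
  labs <- tolower(trimws(labs))
  labs[nzchar(labs)]
}

#' Summarize disease associations of miRNA loci
#'
#' Deduplicated counts over an association table: how many distinct miRNAs
#' lie in LD with a disease SNP, how many distinct SNPs are involved, and
#' how many unique phenotypes those SNPs carry (labels case-folded and
#' whitespace-trimmed; multiple phenotypes per SNP separated by `;`).
#'
#' @param associations Output of [intersect_mirna_ld()].
#' @param snps Disease-SNP catalog with `rsid` and `phenotype` columns.
#' @return List: `n_mirna_in_ld`, `n_unique_snps`, `n_unique_phenotypes`.
#' @export
summarize_disease <- function(associations, snps) {
  if (nrow(associations) == 0L)
    return(list(n_mirna_in_ld = 0L, n_unique_snps = 0L,
                n_unique_phenotypes = 0L))
  rsids <- unique(associations$index_rsid)
  phen <- unique(normalize_phenotypes(
    snps$phenotype[snps$rsid %in% rsids]))
  list(n_mirna_in_ld = length(unique(associations$mirna)),
       n_unique_snps = length(rsids),
       n_unique_phenotypes = length(phen))
}

#' Common-SNP overlap of mature miRNAs
#'
#' Flags each mature miRNA whose genomic interval contains at least one
#' SNP with minor-allele frequency at or above `maf_min` (position within
#' `[start, end)`; the MAF boundary is inclusive).
#'
#' @param mirnas Interval `data.frame` with `name` column.
#' @param snps SNP catalog with `chrom`, `pos`, `maf`.
#' @param maf_min Common-SNP MAF cutoff (e.g. 0.01 or 0.05).
#' @return Named logical vector over the miRNAs, with attribute `n_flagged`.
#' @export
common_snp_overlap <- function(mirnas, snps, maf_min = 0.01) {
  common <- snps[snps$maf >= maf_min, , drop = FALSE]
  flags <- vapply(seq_len(nrow(mirnas)), function(i) {
    any(common$chrom == mirnas$chrom[i] &
          common$pos >= mirnas$start[i] & common$pos < mirnas$end[i])
  }, logical(1))
  names(flags) <- mirnas$name
  attr(flags, "n_flagged") <- sum(flags)
  flags
}
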