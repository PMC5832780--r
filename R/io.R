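#' Read haplotype or query sequences from a FASTA file
#'
#' Reads every record of a FASTA file, uppercases the sequence, and maps RNA
#' `U` to the canonical DNA `T` (all storage in this package is DNA-side;
#' RNA-facing display converts back).  Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA sequence per record, in
#'   file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), tf)
#' read_fasta(tf) # c(x = "ACGT")
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate record name: ", nm[duplicated(nm)][1])
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  ok <- grepl("^[ACGTN]+$", seqs)
  if (!all(ok))
    stop("illegal characters in record '", nm[!ok][1], "'")
  setNames(seqs, nm)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' `N` maps to `N`; the operation is an involution.  Accepts `U` as `T`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(seq) {
  seq <- chartr("Uu", "Tt", seq)
  bad <- !grepl("^[ACGTNacgtn]*$", seq)
  if (any(bad)) stop("non-DNA character in sequence ", which(bad)[1])
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a validated interval table
#'
#' Intervals are 0-based, half-open (BED convention) throughout the package.
#'
#' @param chrom Chromosome / sequence identifiers.
#' @param start,end Integer offsets, `0 <= start < end`.
#' @param strand `"+"` or `"-"` (recycled).
#' @param name Optional feature names.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (and `name` if given).
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+", name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("negative start")
  if (any(end <= start)) stop("end must exceed start (0-based, half-open)")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = rep_len(strand, length(start)),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  df
}

# interval data.frame <-> GRanges (internal; GRanges is 1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Merge overlapping intervals
#'
#' Collapses overlapping (not merely abutting-by-zero; half-open abutment
#' *is* merged, as BED merging does) intervals into their union.  Strand is
#' ignored by default, matching how the locus atlas merges entries; set
#' `stranded = TRUE` to merge within strands only.
#'
#' @param intervals Interval `data.frame` (see [genomic_intervals()]).
#' @param stranded Merge per strand instead of strand-blind.
#' @return Merged interval `data.frame`, sorted by (chrom, start, end).
#' @examples
#' merge_intervals(genomic_intervals("c", c(0, 50), c(100, 150)))
#' @export
merge_intervals <- function(intervals, stranded = FALSE) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0))[0, ])
  gr <- as_granges(intervals)
  red <- GenomicRanges::reduce(gr, ignore.strand = !stranded)
  out <- from_granges(GenomicRanges::sort(red, ignore.strand = !stranded))
  if (!stranded) out$strand <- "+"
  out
}

#' Read and write BED6 interval files
#'
#' Plain-text BED with columns chrom, start, end, name, score, strand;
#' coordinates stay 0-based half-open.  Writers emit rows sorted by
#' (chrom, start, end, name) so output is deterministic.
#'
#' @param path File path.
#' @param intervals Interval `data.frame`; missing `name`/`score` columns are
#'   filled with `"."` and `0`.
#' @return `read_bed`: an interval `data.frame` with `name` and `score`;
#'   `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(min(ncol(df), 6L))]
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "+"
  df[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  df <- intervals
  if (!"name" %in% names(df)) df$name <- rep(".", nrow(df))
  if (!"score" %in% names(df)) df$score <- rep(0, nrow(df))
  if (!"strand" %in% names(df)) df$strand <- rep("+", nrow(df))
  df <- df[order(df$chrom, df$start, df$end, df$name),
           c("chrom", "start", "end", "name", "score", "strand")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read exon intervals from a BED or GFF3/GTF annotation
#'
#' GFF3/GTF input is restricted to `exon` feature rows; BED input is taken
#' as-is.  Coordinates are returned 0-based half-open.
#'
#' @param path Annotation file (`.bed`, `.gff`, `.gff3`, `.gtf`).
#' @return Interval `data.frame`.
#' @export
read_exons <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- read_bed(path)
    return(df[, c("chrom", "start", "end", "strand")])
  }
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  df <- from_granges(gr)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df
}
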