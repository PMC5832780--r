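#' Find every exact occurrence of a query in a haplotype sequence
#'
#' Reports each position where the query, or its reverse complement, occurs
#' as an exact full-length substring of the haplotype — the 100%-identity,
#' full-query-length criterion.  (Under that criterion an exact substring
#' search is equivalent to a BLAST search filtered to perfect full-length
#' hits: any such hit is an exact occurrence and vice versa, so no
#' alignment heuristic is involved.)  Overlapping occurrences are all
#' reported.  RNA queries (with `U`) are normalized to DNA first.
#'
#' @param query Character scalar, length >= 1.
#' @param hap Haplotype sequence (character scalar).
#' @return `data.frame` with `position` (0-based start on the forward
#'   strand) and `strand`; zero rows when absent.
#' @examples
#' find_exact("CGT", "AACGTT")
#' @export
find_exact <- function(query, hap) {
  query <- chartr("Uu", "Tt", toupper(query))
  hap <- chartr("Uu", "Tt", toupper(hap))
  if (nchar(query) < 1L) stop("empty query")
  subj <- Biostrings::DNAString(hap)
  hit_starts <- function(q) {
    Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(q), subj))
  }
  fwd <- hit_starts(query)
  rev <- hit_starts(revcomp(query))
  out <- data.frame(
    position = c(fwd, rev) - 1L,
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Presence/absence of query sequences across haplotypes
#'
#' Builds the conservation matrix underlying cross-haplotype comparisons: a
#' query is *present* in a haplotype iff it has at least one exact
#' full-length match on either strand.  Row and column order follow the
#' input order.
#'
#' @param queries Named character vector of query sequences (mature or
#'   precursor); names must be unique.
#' @param haps Named character vector of haplotype sequences.
#' @return Logical matrix (queries x haplotypes) of class
#'   `presence_matrix`, with attribute `hits`: a list (by query, then
#'   haplotype) of the hit tables from [find_exact()].
#' @export
presence_matrix <- function(queries, haps) {
  if (anyDuplicated(names(queries)))
    stop("duplicate query ids: ",
         names(queries)[duplicated(names(queries))][1])
  m <- matrix(FALSE, nrow = length(queries), ncol = length(haps),
              dimnames = list(names(queries), names(haps)))
  hits <- lapply(seq_along(queries), function(qi) {
    lapply(seq_along(haps), function(hi) find_exact(queries[[qi]], haps[[hi]]))
  })
  if (length(queries))
    for (qi in seq_along(queries))
      for (hi in seq_along(haps))
        m[qi, hi] <- nrow(hits[[qi]][[hi]]) > 0L
  structure(m, hits = hits, class = c("presence_matrix", class(m)))
}

#' Write a presence/absence matrix as TSV
#'
#' @param m A [presence_matrix()].
#' @param path Output path; cells are written `present`/`absent`.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   ifelse(unclass(m), "present", "absent"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-haplotype conservation of candidate loci
#'
#' Pairs a locus from set A with a locus from set B whenever the shorter of
#' the two sequences occurs exactly (on either strand) within the longer —
#' 100% identity over the length of the shorter sequence.  A locus of A
#' counts as conserved iff it has at least one partner in B.
#'
#' @param loci_a,loci_b Named character vectors of locus sequences.
#' @return `data.frame` with `id_a`, `id_b`, one row per conserved pair;
#'   attribute `conserved_a`: logical vector over `loci_a`.
#' @export
conserved_locus_pairs <- function(loci_a, loci_b) {
  norm <- function(x) chartr("Uu", "Tt", toupper(x))
  loci_a <- norm(loci_a)
  loci_b <- norm(loci_b)
  rows <- list()
  for (ia in seq_along(loci_a)) {
    a <- loci_a[[ia]]
    for (ib in seq_along(loci_b)) {
      b <- loci_b[[ib]]
      if (nchar(a) <= nchar(b)) {
        q <- a; s <- b
      } else {
        q <- b; s <- a
      }
      if (grepl(q, s, fixed = TRUE) || grepl(revcomp(q), s, fixed = TRUE))
        rows[[length(rows) + 1L]] <- c(names(loci_a)[ia], names(loci_b)[ib])
    }
  }
  out <- if (length(rows)) {
    data.frame(id_a = vapply(rows, `[`, "", 1),
               id_b = vapply(rows, `[`, "", 2), stringsAsFactors = FALSE)
  } else data.frame(id_a = character(0), id_b = character(0),
                    stringsAsFactors = FALSE)
  cons <- names(loci_a) %in% out$id_a
  names(cons) <- names(loci_a)
  attr(out, "conserved_a") <- cons
  out
}
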