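#' Scoring scheme for semi-global alignment
#'
#' Match/mismatch scoring over `{A, C, G, T/U, N}` with a linear gap
#' penalty and penalty-free terminal gaps at both ends of both sequences
#' (overlap alignment, suited to short end-overlapping sequences).  `U` and
#' `T` are the same symbol; `N` scores 0 against everything.
#'
#' @param match Match score (default +5).
#' @param mismatch Mismatch score (default -4).
#' @param gap Penalty per gap position, subtracted (default 8, so >= 0).
#' @return A list of class `scoring_scheme` with a `matrix` component.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap = 8) {
  if (gap < 0) stop("gap penalty is subtracted and must be >= 0")
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  structure(list(matrix = m, gap = gap), class = "scoring_scheme")
}

#' Semi-global (overlap) pairwise alignment
#'
#' Needleman-Wunsch dynamic program with free terminal gaps: the first row
#' and column cost nothing and the score is the maximum over the last row
#' and column, so either sequence may overhang either end unpenalized.
#' Traceback is deterministic with the fixed tie rule diagonal, then up
#' (gap in `b`), then left (gap in `a`).
#'
#' @param a,b Non-empty nucleotide strings (`U` treated as `T`).
#' @param scheme A [scoring_scheme()].
#' @return A list of class `alignment_result`: `score`, `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `identity` (fraction of
#'   aligned columns in which both sequences agree).
#' @examples
#' semiglobal_align("CGT", "ACGTA")$score # 15: free end gaps on the subject
#' @export
semiglobal_align <- function(a, b, scheme = scoring_scheme()) {
  a <- chartr("Uu", "Tt", toupper(a))
  b <- chartr("Uu", "Tt", toupper(b))
  if (nchar(a) < 1L || nchar(b) < 1L) stop("empty sequence")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (!all(c(ca, cb) %in% rownames(scheme$matrix)))
    stop("sequence contains characters outside the scoring alphabet")
  n <- length(ca)
  m <- length(cb)
  g <- scheme$gap
  S <- matrix(0, n + 1L, m + 1L) # free leading gaps
  for (i in seq_len(n)) {
    sub <- scheme$matrix[ca[i], cb]
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] - g,
                               S[i + 1L, j] - g)
    }
  }
  # best end point on the bottom row / right column (free trailing gaps)
  last_col <- S[, m + 1L]
  last_row <- S[n + 1L, ]
  if (max(last_col) >= max(last_row)) {
    ei <- which.max(last_col) - 1L
    ej <- m
  } else {
    ei <- n
    ej <- which.max(last_row) - 1L
  }
  score <- S[ei + 1L, ej + 1L]
  # traceback: trailing free gaps first, then DP cells, then leading gaps
  al_a <- character(0)
  al_b <- character(0)
  if (ei < n) {
    al_a <- ca[seq(n, ei + 1L)]
    al_b <- rep("-", n - ei)
  }
  if (ej < m) {
    al_a <- c(al_a, rep("-", m - ej))
    al_b <- c(al_b, cb[seq(m, ej + 1L)])
  }
  i <- ei
  j <- ej
  while (i > 0L && j > 0L) {
    if (abs(S[i + 1L, j + 1L] -
            (S[i, j] + scheme$matrix[ca[i], cb[j]])) < 1e-9) {
      al_a <- c(al_a, ca[i]); al_b <- c(al_b, cb[j])
      i <- i - 1L; j <- j - 1L
    } else if (abs(S[i + 1L, j + 1L] - (S[i, j + 1L] - g)) < 1e-9) {
      al_a <- c(al_a, ca[i]); al_b <- c(al_b, "-")
      i <- i - 1L
    } else {
      al_a <- c(al_a, "-"); al_b <- c(al_b, cb[j])
      j <- j - 1L
    }
  }
  if (i > 0L) {
    al_a <- c(al_a, ca[seq(i, 1L)])
    al_b <- c(al_b, rep("-", i))
  }
  if (j > 0L) {
    al_a <- c(al_a, rep("-", j))
    al_b <- c(al_b, cb[seq(j, 1L)])
  }
  al_a <- rev(al_a)
  al_b <- rev(al_b)
  both <- al_a != "-" & al_b != "-"
  identity <- if (any(both)) sum(al_a[both] == al_b[both]) / sum(both) else 0
  structure(list(score = score,
                 aligned_a = paste(al_a, collapse = ""),
                 aligned_b = paste(al_b, collapse = ""),
                 identity = identity),
            class = "alignment_result")
}

#' Best-scoring annotated matches of a novel miRNA
#'
#' Aligns one novel mature miRNA against every catalog entry and reports
#' the closest match(es): every catalog entry achieving the maximal
#' alignment score is returned, in catalog order, so ties are never
#' silently dropped.
#'
#' @param novel Character scalar, the novel mature sequence.
#' @param catalog Named character vector of annotated mature sequences.
#' @param scheme A [scoring_scheme()].
#' @return `data.frame` with `catalog_id`, `score`, `identity`,
#'   `aligned_query`, `aligned_subject`, one row per tied best hit.
#' @export
best_annotated_matches <- function(novel, catalog, scheme = scoring_scheme()) {
  if (length(catalog) == 0L) stop("empty catalog")
  res <- lapply(catalog, semiglobal_align, a = novel, scheme = scheme)
  scores <- vapply(res, `[[`, numeric(1), "score")
  best <- which(scores == max(scores))
  data.frame(catalog_id = names(catalog)[best],
             score = scores[best],
             identity = vapply(res[best], `[[`, numeric(1), "identity"),
             aligned_query = vapply(res[best], `[[`, "", "aligned_a"),
             aligned_subject = vapply(res[best], `[[`, "", "aligned_b"),
             row.names = NULL, stringsAsFactors = FALSE)
}
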