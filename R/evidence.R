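#' @title Functional evidence: Ago CLIP read support and Dicer dependence
#' @name evidence
NULL

# Lenient 4-line FASTQ reader: malformed records are skipped (with a
# warning giving the count) rather than aborting the whole file, so one
# truncated record in a large public CLIP dataset does not kill a run.
read_fastq_seqs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  dropped <- length(lines) - n_rec * 4L
  if (n_rec == 0L) {
    if (dropped > 0L) warning("no complete FASTQ records in ", path)
    return(character(0))
  }
  recs <- matrix(lines[seq_len(n_rec * 4L)], nrow = 4L)
  ok <- startsWith(recs[1L, ], "@") & startsWith(recs[3L, ], "+") &
    nchar(recs[2L, ]) == nchar(recs[4L, ]) &
    grepl("^[ACGTUNacgtun]*$", recs[2L, ])
  bad <- sum(!ok) + as.integer(dropped > 0L)
  if (bad > 0L)
    warning(bad, " malformed FASTQ record(s) skipped in ", path)
  chartr("Uu", "Tt", toupper(recs[2L, ok]))
}

#' Count exact read support for a mature miRNA across CLIP datasets
#'
#' For each read set, counts the reads that contain the exact, ungapped
#' mature sequence as a substring (sense orientation by default, since
#' CLIP reads are sequenced in the sense of the bound RNA).  A miRNA is
#' *supported* when its read count reaches the threshold — by default 500
#' reads summed over all datasets; `per_dataset = TRUE` applies the
#' stricter reading that every dataset must individually reach it.
#'
#' @param mirna_seq Mature miRNA sequence (>= 16 nt; `U` read as `T`).
#' @param datasets Character vector of FASTQ paths (plain or gzip), or a
#'   list of character vectors of read sequences.
#' @param threshold Supporting-read threshold (default 500).
#' @param both_strands Also count reads containing the reverse complement.
#' @param per_dataset Require the threshold within every dataset instead of
#'   on the summed total.
#' @return A list of class `ago_support`: `counts` (per dataset), `total`,
#'   `supported`, `threshold`.
#' @export
count_read_support <- function(mirna_seq, datasets, threshold = 500L,
                               both_strands = FALSE, per_dataset = FALSE) {
  mirna_seq <- chartr("Uu", "Tt", toupper(mirna_seq))
  if (nchar(mirna_seq) < 16L)
    stop("mature miRNA sequence must be at least 16 nt")
  get_reads <- function(d) if (is.character(d) && length(d) == 1L &&
                                 file.exists(d)) read_fastq_seqs(d) else
                                   chartr("Uu", "Tt", toupper(d))
  counts <- vapply(datasets, function(d) {
    reads <- get_reads(d)
    hit <- grepl(mirna_seq, reads, fixed = TRUE)
    if (both_strands)
      hit <- hit | grepl(revcomp(mirna_seq), reads, fixed = TRUE)
    sum(hit)
  }, integer(1))
  if (is.character(datasets)) names(counts) <- basename(datasets)
  flag <- flag_supported(counts, threshold = threshold,
                         per_dataset = per_dataset)
  structure(list(counts = counts, total = sum(counts), supported = flag,
                 threshold = threshold), class = "ago_support")
}

#' Apply the supporting-read threshold
#'
#' @param counts Integer vector of per-dataset read counts for one miRNA
#'   (or a list of such vectors for several).
#' @param threshold Minimum supporting reads (reached counts as supported:
#'   "500 reads or more").
#' @param per_dataset Require the threshold in each dataset rather than on
#'   the sum.
#' @return Logical flag (or vector of flags).
#' @export
flag_supported <- function(counts, threshold = 500L, per_dataset = FALSE) {
  one <- function(x) {
    if (length(x) == 0L) return(FALSE)
    if (per_dataset) all(x >= threshold) else sum(x) >= threshold
  }
  if (is.list(counts)) vapply(counts, one, logical(1)) else one(counts)
}

#' Dicer-dependence calls from a qPCR Ct table
#'
#' For each target, computes per-sample delta-Ct against the normalizer
#' (`Ct_target - Ct_normalizer`; larger delta-Ct = lower expression), then
#' a two-sided pooled-variance t-test between the silenced and control
#' conditions.  A target is called Dicer-dependent when the test is
#' significant (`p <= alpha`) *and* expression fell upon silencing
#' (silenced mean delta-Ct above control): attenuation in the wrong
#' direction is never flagged.  Fold change is reported as
#' `2^-(delta-delta-Ct)`.
#'
#' @param ct_table `data.frame` with columns `sample`, `condition`,
#'   `target`, `ct`.
#' @param normalizer Target name of the normalizer gene (e.g. beta-actin).
#' @param silenced,control Condition labels.
#' @param alpha Significance level (the boundary itself is significant:
#'   `p <= alpha`).
#' @return `data.frame`, one row per non-normalizer target: `target`,
#'   `mean_dct_control`, `mean_dct_silenced`, `ddct`, `fold_change`,
#'   `p_value`, `dependent`.  Targets missing a normalizer Ct in any of
#'   their samples are skipped with a warning.
#' @export
dicer_dependence_test <- function(ct_table, normalizer = "ACTB",
                                  silenced = "silenced", control = "control",
                                  alpha = 0.05) {
  stopifnot(all(c("sample", "condition", "target", "ct") %in% names(ct_table)))
  norm <- ct_table[ct_table$target == normalizer, ]
  if (nrow(norm) == 0L) stop("normalizer '", normalizer, "' absent from table")
  norm_ct <- setNames(norm$ct, norm$sample)
  targets <- setdiff(unique(ct_table$target), normalizer)
  rows <- lapply(targets, function(tg) {
    sub <- ct_table[ct_table$target == tg, ]
    if (!all(sub$sample %in% names(norm_ct))) {
      warning("target ", tg, " skipped: normalizer Ct missing for sample(s) ",
              paste(setdiff(sub$sample, names(norm_ct)), collapse = ", "))
      return(NULL)
    }
    dct <- sub$ct - norm_ct[sub$sample]
    ds <- dct[sub$condition == silenced]
    dc <- dct[sub$condition == control]
    if (length(ds) < 2L || length(dc) < 2L) {
      warning("target ", tg, " skipped: fewer than 2 replicates per condition")
      return(NULL)
    }
    p <- tryCatch(t.test(ds, dc, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_) # constant data: no evidence
    ddct <- mean(ds) - mean(dc)
    data.frame(target = tg,
               mean_dct_control = mean(dc), mean_dct_silenced = mean(ds),
               ddct = ddct, fold_change = 2^(-ddct), p_value = p,
               dependent = !is.na(p) && p <= alpha && mean(ds) > mean(dc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(target = character(0), mean_dct_control = numeric(0),
                      mean_dct_silenced = numeric(0), ddct = numeric(0),
                      fold_change = numeric(0), p_value = numeric(0),
                      dependent = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
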