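#' Configuration for the hairpin-locus scan
#'
#' Defaults are the published study settings: windows of 58-110 nt at a
#' 1 bp stride on both strands, kept when the window folds below
#' -20 kcal/mol (strictly: windows at or above the cutoff are removed) into
#' a topology with exactly one hairpin loop, no multiloop and no bulge
#' (internal loops tolerated).  The 58/110/-20 defaults correspond to the
#' 5th/95th percentiles of annotated human pre-miRNA length and MFE
#' distributions; [derive_cutoffs()] recomputes them from any catalog.
#'
#' @param min_len,max_len Window length bounds in nt.
#' @param stride Start-offset stride in bp.
#' @param mfe_cutoff Free-energy cutoff in kcal/mol.
#' @param strict_less Keep windows with `mfe < cutoff` (`TRUE`, the
#'   operational reading "MFE >= -20 removed") or `mfe <= cutoff`.
#' @param strand `"both"`, `"+"` or `"-"`.
#' @param prescreen Enable the conservative complementarity prescreen:
#'   windows whose Nussinov maximum pair count is below
#'   `prescreen_min_pairs` are never folded.
#' @param prescreen_min_pairs Pair-count bound; if `NULL`, derived from the
#'   energy model as `floor(|cutoff| / max|stack|) + 1`, which no structure
#'   reaching the cutoff can undercut (every negative energy term is a
#'   stack, and a structure with p pairs has at most p - 1 stacks), so the
#'   screen provably never changes the final atlas.
#' @param reject_bulges,reject_multiloops,reject_internal_loops Topology
#'   strictness flags applied to the MFE structure of each window.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(min_len = 58L, max_len = 110L, stride = 1L,
                        mfe_cutoff = -20, strict_less = TRUE,
                        strand = c("both", "+", "-"),
                        prescreen = TRUE, prescreen_min_pairs = NULL,
                        reject_bulges = TRUE, reject_multiloops = TRUE,
                        reject_internal_loops = FALSE) {
  strand <- match.arg(strand)
  if (min_len > max_len) stop("min_len must not exceed max_len")
  if (stride < 1L) stop("stride must be >= 1")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 stride = as.integer(stride), mfe_cutoff = mfe_cutoff,
                 strict_less = strict_less, strand = strand,
                 prescreen = prescreen,
                 prescreen_min_pairs = prescreen_min_pairs,
                 reject_bulges = reject_bulges,
                 reject_multiloops = reject_multiloops,
                 reject_internal_loops = reject_internal_loops),
            class = "scan_config")
}

prescreen_bound <- function(config, params) {
  if (!config$prescreen) return(0L)
  if (!is.null(config$prescreen_min_pairs))
    return(as.integer(config$prescreen_min_pairs))
  as.integer(floor(abs(config$mfe_cutoff) / max(abs(params$stack)))) + 1L
}

#' Enumerate all candidate windows of a sequence
#'
#' For every admissible start offset and every length in
#' `[min_len, max_len]`, emits the forward-strand window and (for
#' `strand = "both"`) its reverse-complement window, both written 5' to 3'
#' on their own strand; minus-strand windows carry the forward-strand
#' interval they occupy.  Order is (start, length, strand).  Identical
#' (interval, strand) windows are emitted once.
#'
#' @param seq Character scalar (one haplotype/region sequence).
#' @param config A [scan_config()].
#' @param chrom Sequence name used in the interval columns.
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`, `seq`.
#' @export
enumerate_windows <- function(seq, config = scan_config(), chrom = "seq") {
  L <- nchar(seq)
  if (L < config$min_len) {
    warning("sequence shorter than min_len; no windows")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  starts <- seq(0L, L - config$min_len, by = config$stride)
  rows <- do.call(rbind, lapply(starts, function(s) {
    lens <- config$min_len:min(config$max_len, L - s)
    data.frame(start = s, end = s + lens, stringsAsFactors = FALSE)
  }))
  strands <- switch(config$strand, both = c("+", "-"), config$strand)
  out <- do.call(rbind, lapply(strands, function(st) {
    df <- rows
    df$strand <- st
    df
  }))
  out <- out[order(out$start, out$end, out$strand), ]
  fwd <- substring(seq, out$start + 1L, out$end)
  out$seq <- ifelse(out$strand == "+", fwd, revcomp(fwd))
  data.frame(chrom = chrom, start = out$start, end = out$end,
             strand = out$strand, seq = out$seq,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Complementarity prescreen for candidate windows
#'
#' Cheap pass/fail gate applied before folding: a window passes when its
#' Nussinov maximum pair count reaches `threshold`.  Because the bound is
#' an upper bound on the pairs of *any* structure, the screen never rejects
#' a window whose true (MFE-structure) pair count reaches the threshold;
#' `threshold = 0` passes everything.
#'
#' @param seqs Character vector of window sequences.
#' @param threshold Minimum pair count.
#' @param min_loop Minimum hairpin-loop size used in the bound.
#' @return Logical vector.
#' @export
prescreen <- function(seqs, threshold, min_loop = 3L) {
  if (threshold <= 0) return(rep(TRUE, length(seqs)))
  vapply(seqs, function(s) max_pair_count(s, min_loop) >= threshold,
         logical(1), USE.NAMES = FALSE)
}

scan_topology_pass <- function(topo, config) {
  topo$n_hairpin_loops == 1L &&
    (!config$reject_multiloops || topo$n_multiloops == 0L) &&
    (!config$reject_bulges || topo$n_bulges == 0L) &&
    (!config$reject_internal_loops || topo$n_internal_loops == 0L)
}

#' Scan a sequence for pre-miRNA-like hairpin windows
#'
#' Stages 1-4 of the discovery pipeline for one sequence: enumerate
#' overlapping windows on both strands, prescreen, fold each window with
#' the reference engine, keep windows below the free-energy cutoff whose
#' MFE structure passes the topology strictness flags (default: exactly one
#' hairpin loop, no multiloop, no bulge).  Folding is batched in C++: one
#' cubic dynamic program per start offset yields the energy of every window
#' length at that start.
#'
#' @param seq Character scalar, or a single named element of a
#'   [read_fasta()] result.
#' @param config A [scan_config()].
#' @param params Energy model for the reference engine.
#' @param chrom Sequence name for the output intervals.
#' @return `data.frame` of passing windows: `chrom`, `start`, `end`,
#'   `strand`, `seq`, `structure`, `mfe`, plus topology counts, with
#'   attribute `stage_counts` (windows enumerated / folded / MFE-passed /
#'   topology-passed).
#' @export
scan_sequence <- function(seq, config = scan_config(),
                          params = default_energy_params(), chrom = "seq") {
  if (length(seq) != 1L) stop("scan_sequence folds one sequence at a time")
  if (!is.null(names(seq)) && identical(chrom, "seq")) chrom <- names(seq)
  seq <- unname(seq)
  L <- nchar(seq)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), structure = character(0),
                      mfe = numeric(0), n_hairpin_loops = integer(0),
                      n_bulges = integer(0), n_internal_loops = integer(0),
                      n_multiloops = integer(0), n_pairs = integer(0),
                      stringsAsFactors = FALSE)
  n_enum <- if (L >= config$min_len) {
    starts <- seq(0L, L - config$min_len, by = config$stride)
    sum(pmin(config$max_len, L - starts) - config$min_len + 1L) *
      ifelse(config$strand == "both", 2L, 1L)
  } else 0L
  if (L < config$min_len) {
    warning("sequence shorter than min_len; empty scan")
    attr(empty, "stage_counts") <- c(enumerated = 0L, mfe_passed = 0L,
                                     topology_passed = 0L)
    return(empty)
  }
  bound <- prescreen_bound(config, params)
  one_strand <- function(s, st) {
    hits <- c_scan(encode_seq(s), params, config$min_len, config$max_len,
                   config$mfe_cutoff, config$strict_less, bound)
    if (nrow(hits) == 0L) return(NULL)
    fstart <- if (st == "+") hits$start else L - hits$start - hits$len
    if (config$stride > 1L) {
      # c_scan enumerates every start; honor the stride on the forward
      # start offset, matching enumerate_windows
      keep <- fstart %% config$stride == 0L
      hits <- hits[keep, , drop = FALSE]
      fstart <- fstart[keep]
      if (nrow(hits) == 0L) return(NULL)
    }
    data.frame(chrom = chrom, start = fstart, end = fstart + hits$len,
               strand = st,
               seq = substring(s, hits$start + 1L, hits$start + hits$len),
               structure = hits$structure, mfe = hits$mfe,
               stringsAsFactors = FALSE)
  }
  parts <- list(NULL, NULL)
  if (config$strand %in% c("both", "+")) parts[[1]] <- one_strand(seq, "+")
  if (config$strand %in% c("both", "-"))
    parts[[2]] <- one_strand(revcomp(seq), "-")
  mfe_hits <- do.call(rbind, parts)
  if (is.null(mfe_hits) || nrow(mfe_hits) == 0L) {
    attr(empty, "stage_counts") <- c(enumerated = n_enum, mfe_passed = 0L,
                                     topology_passed = 0L)
    return(empty)
  }
  topo <- lapply(mfe_hits$structure, classify_topology)
  keep <- vapply(topo, scan_topology_pass, logical(1), config = config)
  out <- mfe_hits[keep, , drop = FALSE]
  tk <- topo[keep]
  out$n_hairpin_loops <- vapply(tk, `[[`, integer(1), "n_hairpin_loops")
  out$n_bulges <- vapply(tk, `[[`, integer(1), "n_bulges")
  out$n_internal_loops <- vapply(tk, `[[`, integer(1), "n_internal_loops")
  out$n_multiloops <- vapply(tk, `[[`, integer(1), "n_multiloops")
  out$n_pairs <- vapply(tk, `[[`, integer(1), "n_pairs")
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- c(enumerated = n_enum,
                                 mfe_passed = nrow(mfe_hits),
                                 topology_passed = nrow(out))
  out
}

#' Remove windows or loci overlapping annotated exons
#'
#' Drops every entry sharing at least one base with any exon interval,
#' strand-blind; half-open abutment (locus end = exon start) is not an
#' overlap.
#'
#' @param entries Interval `data.frame` (windows or atlas loci).
#' @param exons Interval `data.frame` of exons, same coordinate system.
#' @return `entries` with overlapping rows removed.
#' @export
exclude_exons <- function(entries, exons) {
  if (is.null(entries) || nrow(entries) == 0L) return(entries)
  if (is.null(exons) || nrow(exons) == 0L) return(entries)
  ov <- GenomicRanges::findOverlaps(as_granges(entries), as_granges(exons),
                                    ignore.strand = TRUE)
  hit <- unique(S4Vectors::queryHits(ov))
  if (length(hit)) entries[-hit, , drop = FALSE] else entries
}

#' Merge passing windows into the candidate-locus atlas
#'
#' Strand-blind merge of all passing hairpin windows into disjoint loci,
#' each annotated with the number of windows merged and the best (lowest)
#' window MFE it contains.
#'
#' @param windows Passing windows from [scan_sequence()].
#' @return `data.frame` of loci: `chrom`, `start`, `end`, `name`,
#'   `n_windows`, `best_mfe`, sorted by (chrom, start).
#' @export
build_atlas <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      n_windows = integer(0), best_mfe = numeric(0),
                      stringsAsFactors = FALSE))
  gr <- as_granges(windows)
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- from_granges(red)
  out$strand <- NULL
  out$n_windows <- lengths(revmap)
  out$best_mfe <- vapply(revmap, function(ix) min(windows$mfe[ix]), numeric(1))
  out <- out[order(out$chrom, out$start, out$end), ]
  out$name <- sprintf("locus_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "n_windows", "best_mfe")]
}

#' Derive scan cutoffs from an annotated pre-miRNA catalog
#'
#' Recomputes the window-length bounds and free-energy cutoff as the
#' 5th/95th percentiles of a catalog's precursor length distribution and
#' the 95th percentile of its MFE distribution, the procedure behind the
#' shipped 58/110/-20 defaults.
#'
#' @param lengths Numeric vector of precursor lengths (nt).
#' @param mfes Numeric vector of precursor MFEs (kcal/mol).
#' @param lower,upper Percentile bounds.
#' @return List with `min_len`, `max_len`, `mfe_cutoff`.
#' @export
derive_cutoffs <- function(lengths, mfes, lower = 0.05, upper = 0.95) {
  list(min_len = as.integer(round(quantile(lengths, lower, names = FALSE))),
       max_len = as.integer(round(quantile(lengths, upper, names = FALSE))),
       mfe_cutoff = unname(quantile(mfes, upper, names = FALSE)))
}
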