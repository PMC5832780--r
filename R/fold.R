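#' @title RNA secondary structure: folding, pair tables, loop decomposition
#' @name folding
#' @rdname folding
NULL

# integer encoding used by the C++ engine: A=0 C=1 G=2 U/T=3 N=4
encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "T"
  code <- match(chars, c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(code))
    stop("illegal character '", chars[which(is.na(code))[1]],
         "' at position ", which(is.na(code))[1])
  code
}

#' Predict the minimum-free-energy secondary structure of one sequence
#'
#' Folds a single RNA (or DNA, read as its transcript) sequence with either
#' the package's self-contained nearest-neighbor dynamic program
#' (`engine = "reference"`) or an external folder adapter
#' (`engine = "vienna"`, which shells out to `RNAfold` at its defaults,
#' 37 degrees C).  The reference engine is deterministic for a fixed
#' sequence and parameter set, forms no pseudoknots, and leaves `N`
#' unpairable; its traceback resolves equal-energy alternatives in a fixed
#' documented case order (interior extension, then hairpin, then multiloop).
#'
#' @param seq Character scalar over `A,C,G,T/U,N`; length 1..200 for the
#'   reference engine (the dynamic program is cubic in length).
#' @param params Energy model, as from [default_energy_params()].  Ignored
#'   by the external engine.
#' @param engine `"reference"` or `"vienna"`.
#' @return A list of class `fold_result`: `seq`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol; 0 when no pair is formed), `engine`.
#' @examples
#' fold_mfe(strrep("A", 60))$mfe # 0: no complementary pairs
#' fold_mfe("GGGGGAAAACCCCC")$structure
#' @export
fold_mfe <- function(seq, params = default_energy_params(),
                     engine = c("reference", "vienna")) {
  engine <- match.arg(engine)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L)
    stop("seq must be a single non-empty string")
  if (engine == "reference") {
    if (nchar(seq) > 200L)
      stop("reference engine is limited to sequences of length <= 200")
    res <- c_fold(encode_seq(seq), params)
  } else {
    res <- fold_vienna(seq)
  }
  structure(list(seq = seq, structure = res$structure,
                 mfe = res$mfe, engine = engine),
            class = "fold_result")
}

# External folder adapter: RNAfold (ViennaRNA) at tool defaults, 37 C.
fold_vienna <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stop("RNAfold not found on PATH; external engine unavailable")
  out <- system2(exe, args = "--noPS", input = chartr("T", "U", toupper(seq)),
                 stdout = TRUE)
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3L) stop("could not parse RNAfold output: ", line)
  list(structure = m[2], mfe = as.numeric(m[3]))
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, " (", sprintf("%.2f", x$mfe),
      " kcal/mol, ", x$engine, " engine)\n", sep = "")
  invisible(x)
}

#' Base-pair table of a dot-bracket structure
#'
#' @param structure Dot-bracket string (characters `(`, `)`, `.`).
#' @return Integer vector the length of the structure; `pt[i]` is the
#'   1-based partner of position `i`, or `NA` if unpaired.
#' @examples
#' pair_table("(())") # 4 3 2 1
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) stop("illegal structure character at position ", bad[1])
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[1])
  pt
}

# children (directly enclosed pairs) of the loop closed by (i, j);
# i = 0, j = n + 1 walks the exterior loop
loop_children <- function(pt, i, j) {
  kids <- matrix(integer(0), ncol = 2)
  k <- i + 1L
  while (k < j) {
    if (!is.na(pt[k]) && pt[k] > k) {
      kids <- rbind(kids, c(k, pt[k]))
      k <- pt[k] + 1L
    } else {
      k <- k + 1L
    }
  }
  kids
}

#' Loop decomposition of a dot-bracket structure
#'
#' Performs the standard secondary-structure loop decomposition: every
#' closing pair defines one loop, classified by the number of branches `k`
#' it encloses and the unpaired runs on either side (`k = 0` hairpin loop;
#' `k = 1` with unpaired bases on exactly one side, bulge; on both sides,
#' internal loop; `k >= 2`, multiloop).  A structure is a *linear hairpin*
#' when it has exactly one hairpin loop, no multiloop, and no bulge;
#' symmetric or asymmetric internal loops are tolerated unless
#' `reject_internal_loops` is set.
#'
#' @param structure Dot-bracket string.
#' @param reject_internal_loops If `TRUE`, internal loops also disqualify a
#'   structure from being a linear hairpin.
#' @return A list of class `topology`: `n_hairpin_loops`, `n_bulges`,
#'   `n_internal_loops`, `n_multiloops`, `n_pairs`, `is_linear_hairpin`.
#' @examples
#' classify_topology("((((....))))")$is_linear_hairpin
#' @export
classify_topology <- function(structure, reject_internal_loops = FALSE) {
  pt <- pair_table(structure)
  n <- length(pt)
  counts <- c(hairpin = 0L, bulge = 0L, internal = 0L, multi = 0L)
  opens <- which(!is.na(pt) & pt > seq_len(n))
  for (i in opens) {
    j <- pt[i]
    kids <- loop_children(pt, i, j)
    k <- nrow(kids)
    if (k == 0L) {
      counts["hairpin"] <- counts["hairpin"] + 1L
    } else if (k == 1L) {
      n1 <- kids[1, 1] - i - 1L
      n2 <- j - kids[1, 2] - 1L
      if (n1 == 0L && n2 == 0L) {
        # stacked pair: helix interior, not a loop
      } else if (n1 == 0L || n2 == 0L) {
        counts["bulge"] <- counts["bulge"] + 1L
      } else {
        counts["internal"] <- counts["internal"] + 1L
      }
    } else {
      counts["multi"] <- counts["multi"] + 1L
    }
  }
  linear <- counts["hairpin"] == 1L && counts["multi"] == 0L &&
    counts["bulge"] == 0L &&
    (!reject_internal_loops || counts["internal"] == 0L)
  structure(list(
    n_hairpin_loops = unname(counts["hairpin"]),
    n_bulges = unname(counts["bulge"]),
    n_internal_loops = unname(counts["internal"]),
    n_multiloops = unname(counts["multi"]),
    n_pairs = length(opens),
    is_linear_hairpin = unname(linear)
  ), class = "topology")
}

#' Re-score a dot-bracket structure under an energy model
#'
#' Standalone loop-decomposition scorer, independent of the dynamic
#' program: decomposes the structure into its loops and sums their energies
#' (stacks, hairpin/bulge/internal initiation, affine multiloop; exterior
#' bases are free).  Used to verify that the energy the engine reports is
#' the energy of the structure it returns, and by the brute-force test
#' oracle.
#'
#' @param seq Sequence the structure annotates.
#' @param structure Dot-bracket string of the same length.
#' @param params Energy model, as from [default_energy_params()].
#' @return Total free energy in kcal/mol (may be `Inf` for structures the
#'   model forbids, e.g. hairpin loops shorter than the minimum).
#' @export
score_structure <- function(seq, structure, params = default_energy_params()) {
  code <- encode_seq(seq)
  if (nchar(structure) != length(code))
    stop("structure and sequence lengths differ")
  pt <- pair_table(structure)
  pair_name <- function(i, j) {
    b <- c("A", "C", "G", "U", "N")
    paste0(b[code[i] + 1L], b[code[j] + 1L])
  }
  ptab <- rownames(params$stack)
  lxc <- params$loop_extrapolation
  # helix-end penalty for AU/UA/GU/UG closing pairs (0 for CG/GC)
  epen <- function(pn) if (pn %in% c("CG", "GC")) 0 else params$terminal_au
  e <- 0
  opens <- which(!is.na(pt) & pt > seq_along(pt))
  for (i in opens) {
    j <- pt[i]
    pn <- pair_name(i, j)
    if (!pn %in% ptab) stop("non-canonical pair ", pn, " at ", i, ",", j)
    kids <- loop_children(pt, i, j)
    k <- nrow(kids)
    if (k == 0L) {
      size <- j - i - 1L
      if (size < params$min_hairpin_loop) return(Inf)
      e <- e + loop_energy(params$hairpin_loop, size, lxc) + epen(pn)
    } else if (k == 1L) {
      n1 <- kids[1, 1] - i - 1L
      n2 <- j - kids[1, 2] - 1L
      inner <- pair_name(kids[1, 1], kids[1, 2])
      if (n1 == 0L && n2 == 0L) {
        e <- e + params$stack[pn, inner]
      } else if (n1 + n2 == 1L) {
        # single-base bulge: flanking helix stacks through the bulge
        e <- e + loop_energy(params$bulge_loop, 1L, lxc) +
          params$stack[pn, inner]
      } else if (n1 == 0L || n2 == 0L) {
        e <- e + loop_energy(params$bulge_loop, n1 + n2, lxc) +
          epen(pn) + epen(inner)
      } else {
        e <- e + loop_energy(params$internal_loop, n1 + n2, lxc) +
          min(params$internal_asymmetry * abs(n1 - n2),
              params$internal_asymmetry_max) +
          epen(pn) + epen(inner)
      }
    } else {
      unpaired <- (j - i - 1L) - sum(kids[, 2] - kids[, 1] + 1L)
      e <- e + params$multiloop_offset +
        params$multiloop_branch * (k + 1L) +
        params$multiloop_unpaired * unpaired +
        epen(pn) + sum(vapply(seq_len(k), function(z)
          epen(pair_name(kids[z, 1], kids[z, 2])), numeric(1)))
    }
  }
  # exterior loop: unpaired bases free, helix-end penalty per external branch
  ext <- loop_children(pt, 0L, length(pt) + 1L)
  if (nrow(ext))
    e <- e + sum(vapply(seq_len(nrow(ext)), function(z)
      epen(pair_name(ext[z, 1], ext[z, 2])), numeric(1)))
  e
}

#' Maximum base-pair count of a sequence (Nussinov bound)
#'
#' Upper bound on the number of canonical pairs any nested structure of the
#' sequence can form, with the configured minimum hairpin-loop size.  Used
#' by the conservative complementarity prescreen in [scan_sequence()].
#'
#' @param seq Character scalar over the DNA/RNA alphabet.
#' @param min_loop Minimum hairpin loop size.
#' @return Integer pair count.
#' @export
max_pair_count <- function(seq, min_loop = 3L) {
  c_max_pairs(encode_seq(seq), as.integer(min_loop))
}
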