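# Independent oracles used by the test suite.  Each re-derives a result by
# brute force or by an algorithm structurally different from the
# implementation it checks, and never calls the code path under test.

# -- folding ----------------------------------------------------------------

# every nested structure over `seq` with canonical pairs and a minimum
# hairpin loop, by exhaustive recursive enumeration (test sizes: n <= 14)
oracle_enum_structures <- function(seq, min_loop = 3L) {
  chars <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  canonical <- c("CG", "GC", "GU", "UG", "AU", "UA")
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (i > j) return("")
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- paste0(".", gen(i + 1L, j))
    ks <- seq(i + min_loop + 1L, j, length.out = max(0L, j - i - min_loop))
    for (k in as.integer(ks)) {
      if (!paste0(chars[i], chars[k]) %in% canonical) next
      out <- c(out, as.vector(outer(paste0("(", gen(i + 1L, k - 1L), ")"),
                                    gen(k + 1L, j), paste0)))
    }
    memo[[key]] <- out
    out
  }
  gen(1L, n)
}

# brute-force MFE: minimum of score_structure over all enumerated
# structures (the all-dot structure, energy 0, is always available)
oracle_brute_mfe <- function(seq, params = default_energy_params()) {
  ss <- oracle_enum_structures(seq, params$min_hairpin_loop)
  min(c(0, vapply(ss, score_structure, numeric(1),
                  seq = seq, params = params)))
}

# random balanced dot-bracket string of length n (any loop sizes)
oracle_random_structure <- function(n, p_pair = 0.35) {
  if (n <= 0L) return("")
  if (n >= 2L && runif(1) < p_pair) {
    k <- sample.int(n - 1L, 1L) - 1L # inside size
    paste0("(", oracle_random_structure(k, p_pair), ")",
           oracle_random_structure(n - 2L - k, p_pair))
  } else {
    paste0(".", oracle_random_structure(n - 1L, p_pair))
  }
}

# stack-based pair table (push/pop), independent of pair_table()
oracle_pair_table <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pt <- rep(NA_integer_, length(chars))
  st <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") st <- c(st, i)
    if (chars[i] == ")") {
      pt[i] <- st[length(st)]
      pt[st[length(st)]] <- i
      st <- st[-length(st)]
    }
  }
  pt
}

# recursive loop decomposition working on substrings and a depth vector,
# structurally independent of classify_topology()
oracle_topology <- function(db) {
  counts <- c(hairpin = 0L, bulge = 0L, internal = 0L, multi = 0L,
              pairs = 0L)
  top_level_pairs <- function(chars) {
    depth <- cumsum((chars == "(") - (chars == ")"))
    opens <- which(chars == "(" & depth == 1L)
    closes <- which(chars == ")" & depth == 0L)
    cbind(opens, closes)
  }
  walk <- function(chars) { # chars: contents strictly inside a pair
    tl <- top_level_pairs(chars)
    k <- nrow(tl)
    if (k == 0L) {
      counts["hairpin"] <<- counts["hairpin"] + 1L
    } else if (k == 1L) {
      left <- tl[1, 1] - 1L
      right <- length(chars) - tl[1, 2]
      if (left + right > 0L) {
        if (left == 0L || right == 0L)
          counts["bulge"] <<- counts["bulge"] + 1L
        else counts["internal"] <<- counts["internal"] + 1L
      }
    } else {
      counts["multi"] <<- counts["multi"] + 1L
    }
    for (z in seq_len(k)) {
      counts["pairs"] <<- counts["pairs"] + 1L
      walk(chars[seq(tl[z, 1] + 1L, length.out = tl[z, 2] - tl[z, 1] - 1L)])
    }
  }
  chars <- strsplit(db, "")[[1]]
  tl <- top_level_pairs(chars)
  for (z in seq_len(nrow(tl))) {
    counts["pairs"] <- counts["pairs"] + 1L
    walk(chars[seq(tl[z, 1] + 1L, length.out = tl[z, 2] - tl[z, 1] - 1L)])
  }
  counts
}

# -- intervals --------------------------------------------------------------

# union of intervals on one chromosome via a per-base boolean mask
oracle_mask_union <- function(starts, ends, limit) {
  mask <- logical(limit)
  for (z in seq_along(starts))
    if (ends[z] > starts[z]) mask[(starts[z] + 1L):ends[z]] <- TRUE
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  data.frame(start = begins[keep] - 1L, end = stops[keep])
}

# does interval [s1,e1) overlap any of the [s2,e2) intervals? (mask-based)
oracle_any_overlap <- function(s1, e1, s2, e2) {
  any(pmax(s1, s2) < pmin(e1, e2))
}

# -- alignment --------------------------------------------------------------

# exhaustive semi-global alignment: enumerate every monotone edit path and
# score it, with gap columns along the leading/trailing DP boundary free
oracle_semiglobal_score <- function(a, b, scheme = scoring_scheme()) {
  ca <- strsplit(chartr("Uu", "Tt", toupper(a)), "")[[1]]
  cb <- strsplit(chartr("Uu", "Tt", toupper(b)), "")[[1]]
  n <- length(ca)
  m <- length(cb)
  g <- scheme$gap
  best <- -Inf
  rec <- function(i, j, acc) {
    if (i == n && j == m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < n && j < m)
      rec(i + 1L, j + 1L, acc + scheme$matrix[ca[i + 1L], cb[j + 1L]])
    if (i < n) { # gap in b; free while on the first or last column of b
      cost <- if (j == 0L || j == m) 0 else -g
      rec(i + 1L, j, acc + cost)
    }
    if (j < m) { # gap in a; free while on the first or last row of a
      cost <- if (i == 0L || i == n) 0 else -g
      rec(i, j + 1L, acc + cost)
    }
  }
  rec(0L, 0L, 0)
  best
}

# -- reads ------------------------------------------------------------------

# naive per-read scan for an exact substring (plain loop over reads)
oracle_count_reads <- function(query, reads) {
  query <- chartr("Uu", "Tt", toupper(query))
  total <- 0L
  for (r in reads)
    if (grepl(query, chartr("Uu", "Tt", toupper(r)), fixed = TRUE))
      total <- total + 1L
  total
}

# pooled two-sample t p-value from first principles
oracle_pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# fraction of truth intervals touched by at least one atlas locus
truth_recovery <- function(atlas, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    any(atlas$start < truth$end[i] & atlas$end > truth$start[i]), logical(1))
}

# independent phenotype-label normalization (split on ';', trim, casefold)
normalize_phenotypes_oracle <- function(x) {
  out <- character(0)
  for (field in x)
    for (lab in strsplit(field, ";")[[1]]) {
      lab <- tolower(gsub("^\\s+|\\s+$", "", lab))
      if (nchar(lab)) out <- c(out, lab)
    }
  out
}
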