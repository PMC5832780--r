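#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  The defaults are
#' the study conditions the test suite runs under: a 2,000-bp haplotype of
#' i.i.d. background at MHC-like GC content (0.41) carrying 5 planted
#' clean hairpins (stems of 20-28 bp, loops of 4-8 nt), a divergent second
#' haplotype at 2% substitution / 0.2% indel rate with half of the hairpin
#' loci protected verbatim, CLIP read sets averaging 600 embedded
#' supporting reads per miRNA plus 400 decoys, a two-replicate qPCR design
#' with a 3-cycle silencing effect at 0.1 cycles of noise, and a SNP/LD
#' catalog of 10 disease SNPs with ~6 proxies each.
#'
#' @param seed Master RNG seed.
#' @param hap_length Haplotype length, bp.
#' @param gc Background GC fraction.
#' @param n_hairpins Planted hairpins per haplotype.
#' @param stem_range,loop_range Stem length / loop size ranges (nt).
#' @param bulge_prob Probability a planted hairpin carries a 1-base bulge.
#' @param subst_rate,indel_rate Inter-haplotype substitution and indel
#'   rates per base (indels never fall inside hairpin loci, so planted
#'   conservation truth stays exact).
#' @param protect_fraction Fraction of hairpin loci copied verbatim into
#'   the second haplotype; unprotected loci are guaranteed at least one
#'   substitution.
#' @param n_mature,mature_len_range Planted mature miRNAs (drawn from
#'   hairpin stems).
#' @param n_datasets,support_mean,n_decoys,read_len CLIP read simulation.
#' @param qpcr_effect,qpcr_sd Silencing effect (cycles) and Ct noise.
#' @param n_disease_snps,phenotypes_per_snp,proxies_per_snp,proxy_span,
#'   r2_range SNP/LD catalog shape.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, hap_length = 2000L, gc = 0.41,
                       n_hairpins = 5L, stem_range = c(20L, 28L),
                       loop_range = c(4L, 8L), bulge_prob = 0,
                       subst_rate = 0.02, indel_rate = 0.002,
                       protect_fraction = 0.5,
                       n_mature = 6L, mature_len_range = c(20L, 24L),
                       n_datasets = 3L, support_mean = 600,
                       n_decoys = 400L, read_len = 36L,
                       qpcr_effect = 3, qpcr_sd = 0.1,
                       n_disease_snps = 10L, phenotypes_per_snp = 1:3,
                       proxies_per_snp = 6L, proxy_span = 300L,
                       r2_range = c(0.6, 1)) {
  stopifnot(gc >= 0, gc <= 1, subst_rate >= 0, subst_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            protect_fraction >= 0, protect_fraction <= 1,
            hap_length > 0, qpcr_effect >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Random i.i.d. DNA sequence at a given GC content
#'
#' Draws from the current RNG stream (seed it with `set.seed()` or via the
#' generator configs).
#'
#' @param n Length in bases.
#' @param gc GC fraction.
#' @return Character scalar.
#' @export
random_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Plant a single hairpin-forming sequence
#'
#' Constructs `arm + loop + revcomp(arm)`, which folds into a clean linear
#' hairpin of at least `stem_len` pairs, optionally corrupted by inserting
#' single bases into the 3' arm (planted bulges).  The arm is drawn
#' GC-rich (0.6) so the construct folds far below the scan's energy
#' cutoff.
#'
#' @param stem_len Stem length in bp (>= 15).
#' @param loop_len Loop size in nt (>= 3).
#' @param n_bulges Number of single-base insertions planted in the 3' arm.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @return List: `seq`, `truth` (stem/loop sizes, bulge count, expected
#'   topology class `"linear"` or `"bulged"`).
#' @export
plant_hairpin <- function(stem_len, loop_len, n_bulges = 0L, seed = NULL) {
  if (stem_len < 15L) stop("stem_len must be >= 15")
  if (loop_len < 3L) stop("loop_len must be >= 3")
  gen <- function() {
    arm <- random_dna(stem_len, gc = 0.6)
    loop <- random_dna(loop_len, gc = 0.3)
    arm2 <- revcomp(arm)
    if (n_bulges > 0L) {
      for (z in seq_len(n_bulges)) {
        at <- sample(3:(nchar(arm2) - 3L), 1L)
        arm2 <- paste0(substr(arm2, 1L, at), random_dna(1L, 0.5),
                       substr(arm2, at + 1L, nchar(arm2)))
      }
    }
    list(seq = paste0(arm, loop, arm2),
         truth = list(stem_len = stem_len, loop_len = loop_len,
                      n_bulges = n_bulges,
                      topology = if (n_bulges > 0L) "bulged" else "linear"))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence while preserving its
#' exact dinucleotide counts, by drawing a random arborescence of
#' last-exit edges in the dinucleotide multigraph and randomizing the
#' remaining edge order.  Used to build structure-free backgrounds with
#' matched composition.
#'
#' @param seq Character scalar.
#' @param seed Optional seed.
#' @return Shuffled sequence of identical length and dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  run <- function() {
    chars <- strsplit(toupper(seq), "")[[1]]
    n <- length(chars)
    if (n < 3L) return(seq)
    verts <- unique(chars)
    last <- chars[n]
    # adjacency: multiset of successors per vertex
    adj <- lapply(setNames(verts, verts),
                  function(v) chars[which(chars[-n] == v) + 1L])
    repeat {
      # pick a random last-exit edge per vertex (except the terminal one);
      # keep only if following these edges from every vertex reaches the
      # terminal vertex (the edges form an arborescence towards it)
      lastexit <- list()
      for (v in verts) {
        if (v == last || length(adj[[v]]) == 0L) next
        lastexit[[v]] <- sample(adj[[v]], 1L)
      }
      reaches_last <- function(v) {
        cur <- v
        for (step in seq_len(length(verts) + 1L)) {
          if (cur == last) return(TRUE)
          nxt <- lastexit[[cur]]
          if (is.null(nxt)) return(FALSE)
          cur <- nxt
        }
        FALSE # cycled
      }
      if (all(vapply(names(lastexit), reaches_last, logical(1)))) break
    }
    shuffled <- lapply(setNames(verts, verts), function(v) {
      pool <- adj[[v]]
      if (!is.null(lastexit[[v]])) {
        # remove one instance of the last-exit edge; append it last
        drop <- match(lastexit[[v]], pool)
        rest <- pool[-drop]
        c(sample(rest), lastexit[[v]])
      } else sample(pool)
    })
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- chars[1]
    for (i in 2:n) {
      v <- out[i - 1L]
      out[i] <- shuffled[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
    }
    paste(out, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a divergent haplotype pair with planted hairpin loci
#'
#' Haplotype A is i.i.d. background carrying non-overlapping planted
#' hairpins at recorded truth intervals.  Haplotype B is derived from A by
#' seeded substitutions and indels at the configured rates, except inside
#' hairpin loci: a `protect_fraction` of hairpins is copied verbatim
#' (conserved), the rest receive at least one guaranteed stem substitution
#' (diverged by construction), and indels never fall within a hairpin
#' locus, so conservation truth is exact.
#'
#' @param config A [sim_config()].
#' @return List of class `hap_pair`: `hap_a`, `hap_b` (named character),
#'   `truth` (`data.frame`: name, start, end, stem_len, loop_len,
#'   protected, seq_a, seq_b), `variants` (`data.frame`: pos_a, ref, alt,
#'   type), `config`.
#' @export
make_haplotype_pair <- function(config = sim_config()) {
  with_seed(config$seed, {
    L <- config$hap_length
    max_hp <- 2L * max(config$stem_range) + max(config$loop_range) + 2L
    if (L < 10L * max_hp)
      stop("hap_length must be at least 10x the maximal hairpin length")
    bg <- random_dna(L, config$gc)
    # draw non-overlapping hairpin positions (margin 20 bp), bounded retries
    margin <- 20L
    hps <- list()
    starts <- integer(0)
    ends <- integer(0)
    for (h in seq_len(config$n_hairpins)) {
      stem <- sample(config$stem_range[1]:config$stem_range[2], 1L)
      loop <- sample(config$loop_range[1]:config$loop_range[2], 1L)
      bul <- rbinom(1L, 1L, config$bulge_prob)
      hp <- plant_hairpin(stem, loop, n_bulges = bul)
      len <- nchar(hp$seq)
      placed <- FALSE
      for (try in 1:200) {
        s <- sample.int(L - len - margin, 1L) + margin %/% 2L
        if (all(s + len + margin <= starts | s >= ends + margin)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place non-overlapping hairpins; ",
                        "increase hap_length or reduce n_hairpins")
      starts <- c(starts, s)
      ends <- c(ends, s + len)
      hps[[h]] <- c(hp, list(start = s, end = s + len,
                             stem = stem, loop = loop))
    }
    ord <- order(starts)
    hps <- hps[ord]
    chars <- strsplit(bg, "")[[1]]
    for (hp in hps)
      chars[(hp$start + 1L):hp$end] <- strsplit(hp$seq, "")[[1]]
    hap_a <- paste(chars, collapse = "")

    n_prot <- round(config$protect_fraction * length(hps))
    protected <- seq_along(hps) <= n_prot  # first n_prot in position order
    in_hairpin <- logical(L)
    for (hp in hps) in_hairpin[(hp$start + 1L):hp$end] <- TRUE

    tokens <- strsplit(hap_a, "")[[1]]
    variants <- list()
    other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    # background substitutions and indels (never inside hairpin loci)
    for (i in seq_len(L)) {
      if (in_hairpin[i]) next
      if (runif(1) < config$subst_rate) {
        alt <- other(tokens[i])
        variants[[length(variants) + 1L]] <-
          data.frame(pos_a = i - 1L, ref = tokens[i], alt = alt,
                     type = "sub", stringsAsFactors = FALSE)
        tokens[i] <- alt
      } else if (runif(1) < config$indel_rate) {
        if (runif(1) < 0.5) {
          variants[[length(variants) + 1L]] <-
            data.frame(pos_a = i - 1L, ref = tokens[i], alt = "",
                       type = "del", stringsAsFactors = FALSE)
          tokens[i] <- ""
        } else {
          ins <- random_dna(1L, config$gc)
          variants[[length(variants) + 1L]] <-
            data.frame(pos_a = i - 1L, ref = tokens[i],
                       alt = paste0(tokens[i], ins), type = "ins",
                       stringsAsFactors = FALSE)
          tokens[i] <- paste0(tokens[i], ins)
        }
      }
    }
    # guaranteed stem substitutions in unprotected hairpins
    for (h in seq_along(hps)) {
      if (protected[h]) next
      hp <- hps[[h]]
      at <- hp$start + sample.int(hp$stem, 1L) # within the 5' arm
      alt <- other(tokens[at])
      variants[[length(variants) + 1L]] <-
        data.frame(pos_a = at - 1L, ref = tokens[at], alt = alt,
                   type = "sub", stringsAsFactors = FALSE)
      tokens[at] <- alt
    }
    hap_b <- paste(tokens, collapse = "")
    truth <- data.frame(
      name = sprintf("hairpin_%02d", seq_along(hps)),
      start = vapply(hps, `[[`, integer(1), "start"),
      end = vapply(hps, `[[`, integer(1), "end"),
      stem_len = vapply(hps, `[[`, integer(1), "stem"),
      loop_len = vapply(hps, `[[`, integer(1), "loop"),
      protected = protected,
      seq_a = vapply(hps, function(hp)
        substr(hap_a, hp$start + 1L, hp$end), character(1)),
      seq_b = vapply(hps, function(hp)
        paste(tokens[(hp$start + 1L):hp$end], collapse = ""), character(1)),
      stringsAsFactors = FALSE)
    structure(list(hap_a = c(hapA = hap_a), hap_b = c(hapB = hap_b),
                   truth = truth,
                   variants = if (length(variants))
                     do.call(rbind, variants)
                   else data.frame(pos_a = integer(0), ref = character(0),
                                   alt = character(0), type = character(0)),
                   config = config),
              class = "hap_pair")
  })
}

#' Simulate Ago CLIP-seq read sets with planted support
#'
#' For each (miRNA, dataset) pair, emits the recorded number of supporting
#' reads, each embedding the exact mature sequence at a random offset
#' inside random flanks, plus decoy reads verified at generation to
#' contain no planted sequence (either strand).  Reads are written as
#' plain FASTQ, one file per dataset.
#'
#' @param mirnas Named character vector of mature sequences.
#' @param counts Integer matrix (miRNA x dataset) of supporting-read
#'   counts, or `NULL` to draw each count as Poisson(`support_mean`).
#' @param config A [sim_config()] (read length, decoys, dataset count,
#'   seed).
#' @param dir Output directory for the FASTQ files.
#' @return List: `paths`, `truth` (the count matrix), `config`.
#' @export
make_clip_reads <- function(mirnas, counts = NULL, config = sim_config(),
                            dir = tempfile("clip")) {
  if (config$read_len < max(nchar(mirnas)))
    stop("read_len must be at least the longest mature sequence")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    nd <- config$n_datasets
    if (is.null(counts)) {
      counts <- matrix(stats::rpois(length(mirnas) * nd, config$support_mean),
                       nrow = length(mirnas),
                       dimnames = list(names(mirnas), NULL))
    }
    forbid <- c(chartr("U", "T", toupper(mirnas)), revcomp(mirnas))
    paths <- character(nd)
    for (d in seq_len(nd)) {
      reads <- character(0)
      for (qi in seq_along(mirnas)) {
        q <- chartr("U", "T", toupper(mirnas[[qi]]))
        k <- counts[qi, d]
        if (k == 0L) next
        flank <- config$read_len - nchar(q)
        offs <- sample.int(flank + 1L, k, replace = TRUE) - 1L
        reads <- c(reads, vapply(offs, function(o)
          paste0(random_dna(o, 0.5), q,
                 random_dna(flank - o, 0.5)), character(1)))
      }
      decoys <- character(config$n_decoys)
      for (z in seq_len(config$n_decoys)) {
        repeat {
          r <- random_dna(config$read_len, 0.5)
          if (!any(vapply(forbid, grepl, logical(1), x = r, fixed = TRUE)))
            break
        }
        decoys[z] <- r
      }
      reads <- sample(c(reads, decoys)) # shuffle read order
      path <- file.path(dir, sprintf("dataset_%02d.fastq", d))
      qual <- strrep("I", config$read_len)
      writeLines(rbind(sprintf("@sim_%02d_%06d", d, seq_along(reads)),
                       reads, "+", qual),
                 path)
      paths[d] <- path
    }
    list(paths = paths, truth = counts, config = config)
  })
}

#' Simulate a two-condition qPCR Ct table
#'
#' Two biological replicates per condition (silencing and scrambled
#' control), one normalizer target (`ACTB`) at a fixed mean Ct, and one
#' row per miRNA target; Dicer-dependent targets gain `qpcr_effect` cycles
#' (lower expression) under silencing.  Gaussian noise of `qpcr_sd` cycles
#' is added to every measured Ct.
#'
#' @param mirna_ids Character vector of target names.
#' @param dependent Logical vector: which targets carry the planted
#'   silencing effect.
#' @param config A [sim_config()] (effect size, noise, seed).
#' @return `data.frame` with `sample`, `condition`, `target`, `ct`, and
#'   attribute `truth` (the `dependent` flags, named).
#' @export
make_qpcr_table <- function(mirna_ids, dependent, config = sim_config()) {
  stopifnot(length(mirna_ids) == length(dependent))
  with_seed(config$seed, {
    samples <- data.frame(
      sample = c("sil_1", "sil_2", "ctl_1", "ctl_2"),
      condition = c("silenced", "silenced", "control", "control"),
      stringsAsFactors = FALSE)
    base_ct <- runif(length(mirna_ids), 20, 26)
    rows <- list(data.frame(sample = samples$sample,
                            condition = samples$condition,
                            target = "ACTB",
                            ct = 15 + rnorm(4L, sd = config$qpcr_sd),
                            stringsAsFactors = FALSE))
    for (i in seq_along(mirna_ids)) {
      eff <- ifelse(samples$condition == "silenced" & dependent[i],
                    config$qpcr_effect, 0)
      rows[[i + 1L]] <- data.frame(
        sample = samples$sample, condition = samples$condition,
        target = mirna_ids[i],
        ct = base_ct[i] + eff + rnorm(4L, sd = config$qpcr_sd),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- setNames(dependent, mirna_ids)
    out
  })
}

#' Simulate a disease-SNP catalog with LD proxy table
#'
#' Places index disease SNPs uniformly on the region, assigns each 1-3
#' phenotype labels from a small pool and a MAF drawn uniform on
#' (0, 0.5), and surrounds each with proxies at uniform offsets within
#' `proxy_span` whose r-squared is uniform over `r2_range`.  The truth
#' sidecar records each block's extent over the proxies with
#' r-squared >= 0.9, computed directly from the drawn values at
#' generation time.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome label for all entries.
#' @param region_len Region length the SNP positions are drawn from.
#' @return List: `snps`, `proxies`, `truth_blocks` (`data.frame` with the
#'   filter-then-extent block bounds), `config`.
#' @export
make_snp_ld_catalog <- function(config = sim_config(), chrom = "hapA",
                                region_len = config$hap_length) {
  with_seed(config$seed + 1L, {
    n <- config$n_disease_snps
    pool <- sprintf("Phenotype %02d", 1:15)
    snps <- data.frame(
      rsid = sprintf("rs%06d", sample.int(999999L, n)),
      chrom = chrom,
      pos = sort(sample.int(region_len, n) - 1L),
      maf = round(runif(n, 0.001, 0.5), 4),
      phenotype = vapply(seq_len(n), function(i)
        paste(sample(pool, sample(config$phenotypes_per_snp, 1L)),
              collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    proxies <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- config$proxies_per_snp
      data.frame(
        index_rsid = snps$rsid[i],
        proxy_rsid = sprintf("%s_p%02d", snps$rsid[i], seq_len(k)),
        pos = pmax(0L, pmin(region_len - 1L,
                            snps$pos[i] + sample(seq(-config$proxy_span,
                                                     config$proxy_span), k))),
        r2 = round(runif(k, config$r2_range[1], config$r2_range[2]), 3),
        stringsAsFactors = FALSE)
    }))
    qual <- proxies[proxies$r2 >= 0.9, ]
    truth_blocks <- do.call(rbind, lapply(seq_len(n), function(i) {
      pos <- c(snps$pos[i], qual$pos[qual$index_rsid == snps$rsid[i]])
      data.frame(index_rsid = snps$rsid[i], start = min(pos),
                 end = max(pos) + 1L, stringsAsFactors = FALSE)
    }))
    list(snps = snps, proxies = proxies, truth_blocks = truth_blocks,
         config = config)
  })
}
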