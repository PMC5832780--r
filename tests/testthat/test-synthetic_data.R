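test_that("planted hairpins fold to their recorded topology class", {
  hp <- plant_hairpin(20, 6, seed = 301)
  f <- fold_mfe(hp$seq)
  topo <- classify_topology(f$structure)
  expect_true(topo$is_linear_hairpin)
  expect_gte(topo$n_pairs, 15L)
  expect_lt(f$mfe, -20)

  hpb <- plant_hairpin(20, 6, n_bulges = 1L, seed = 302)
  fb <- fold_mfe(hpb$seq)
  expect_gte(classify_topology(fb$structure)$n_bulges, 1L)
  expect_equal(hpb$truth$topology, "bulged")

  expect_identical(plant_hairpin(20, 6, seed = 5)$seq,
                   plant_hairpin(20, 6, seed = 5)$seq)
  expect_error(plant_hairpin(10, 6), ">= 15")
  expect_error(plant_hairpin(20, 2), ">= 3")
})

test_that("dinucleotide shuffle preserves exact dinucleotide counts", {
  set.seed(311)
  dn_counts <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(table(paste0(ch[-length(ch)], ch[-1])))
  }
  for (z in 1:5) {
    s <- random_dna(400, runif(1, 0.3, 0.6))
    sh <- dinucleotide_shuffle(s, seed = z)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dn_counts(sh), dn_counts(s))
    expect_false(identical(sh, s))
  }
  expect_identical(dinucleotide_shuffle("ACGTACGTACGT", seed = 3),
                   dinucleotide_shuffle("ACGTACGTACGT", seed = 3))
})

test_that("haplotype pairs carry exact planted and divergence truth", {
  cfg <- sim_config(seed = 21)
  hp <- make_haplotype_pair(cfg)
  expect_equal(nrow(hp$truth), cfg$n_hairpins)
  # truth intervals carry the planted sequences
  for (i in seq_len(nrow(hp$truth)))
    expect_equal(substr(hp$hap_a[[1]], hp$truth$start[i] + 1,
                        hp$truth$end[i]), hp$truth$seq_a[i])
  # protected loci are copied verbatim, unprotected ones differ
  expect_true(all((hp$truth$seq_a == hp$truth$seq_b) == hp$truth$protected))
  # determinism
  hp2 <- make_haplotype_pair(cfg)
  expect_identical(hp$hap_a, hp2$hap_a)
  expect_identical(hp$hap_b, hp2$hap_b)

  # zero divergence: the haplotypes are identical
  same <- make_haplotype_pair(sim_config(seed = 3, subst_rate = 0,
                                         indel_rate = 0,
                                         protect_fraction = 1))
  expect_equal(unname(same$hap_a), unname(same$hap_b))
  pairs <- conserved_locus_pairs(setNames(same$truth$seq_a, same$truth$name),
                                 setNames(same$truth$seq_b,
                                          paste0(same$truth$name, "_b")))
  expect_equal(sum(attr(pairs, "conserved_a")), nrow(same$truth))
})

test_that("CLIP read generation matches its truth sidecar", {
  set.seed(321)
  mirs <- c(m1 = random_dna(20, .5), m2 = random_dna(22, .5))
  cfg <- sim_config(seed = 31, n_datasets = 2L, n_decoys = 60L)
  counts <- matrix(c(40L, 0L, 10L, 25L), nrow = 2,
                   dimnames = list(names(mirs), NULL))
  clip <- make_clip_reads(mirs, counts = counts, config = cfg)
  for (qi in 1:2) for (d in 1:2) {
    got <- count_read_support(mirs[[qi]], clip$paths[d], threshold = 1)
    expect_equal(unname(got$counts), unname(counts[qi, d]))
  }
  # byte-identical regeneration under the same seed
  clip2 <- make_clip_reads(mirs, counts = counts, config = cfg,
                           dir = tempfile("clip2"))
  expect_identical(readLines(clip$paths[1]), readLines(clip2$paths[1]))
})

test_that("qPCR tables plant the silencing effect where instructed", {
  cfg <- sim_config(seed = 41)
  tab <- make_qpcr_table(c("m1", "m2"), c(TRUE, FALSE), cfg)
  expect_identical(tab, make_qpcr_table(c("m1", "m2"), c(TRUE, FALSE), cfg))
  res <- dicer_dependence_test(tab)
  expect_equal(res$dependent[res$target == "m1"], TRUE)
  expect_equal(res$dependent[res$target == "m2"], FALSE)
  expect_equal(res$ddct[res$target == "m1"], cfg$qpcr_effect,
               tolerance = 0.5)
})

test_that("SNP/LD catalogs record computable truth blocks", {
  cfg <- sim_config(seed = 51)
  cat1 <- make_snp_ld_catalog(cfg)
  b <- build_ld_blocks(cat1$proxies, cat1$snps, r2_min = 0.9)
  expect_equal(b$start, cat1$truth_blocks$start)
  expect_equal(b$end, cat1$truth_blocks$end)
  cat2 <- make_snp_ld_catalog(cfg)
  expect_identical(cat1$snps, cat2$snps)
  expect_identical(cat1$proxies, cat2$proxies)
  # all proxies below 0.9: blocks collapse to the index position
  low <- cat1$proxies
  low$r2 <- 0.5
  b0 <- build_ld_blocks(low, cat1$snps, r2_min = 0.9)
  expect_true(all(b0$end - b0$start == 1L))
  expect_equal(b0$start, cat1$snps$pos)
})

test_that("atlas density shrinks as the MFE cutoff tightens", {
  set.seed(331)
  hp <- plant_hairpin(24, 6)$seq
  seq <- paste0(random_dna(100, .41), hp, random_dna(100, .41))
  n_relaxed <- nrow(scan_sequence(seq, scan_config(mfe_cutoff = -15)))
  n_default <- nrow(scan_sequence(seq, scan_config(mfe_cutoff = -20)))
  n_tight <- nrow(scan_sequence(seq, scan_config(mfe_cutoff = -35)))
  expect_gte(n_relaxed, n_default)
  expect_gte(n_default, n_tight)
})
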