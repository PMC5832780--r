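snp_cat <- function(pos, rsid = sprintf("rs%03d", seq_along(pos)),
                    maf = 0.2, phen = "Phenotype A") {
  data.frame(rsid = rsid, chrom = "c", pos = pos, maf = maf,
             phenotype = phen, stringsAsFactors = FALSE)
}

test_that("LD blocks span the index and qualifying proxies only", {
  snps <- snp_cat(1000L)
  prox <- data.frame(index_rsid = "rs001",
                     proxy_rsid = c("p1", "p2"),
                     pos = c(800L, 1200L), r2 = c(0.95, 0.91),
                     stringsAsFactors = FALSE)
  b <- build_ld_blocks(prox, snps)
  expect_equal(b$start, 800L)
  expect_equal(b$end, 1201L)
  expect_equal(b$n_proxies, 2L)

  # r2 below threshold: block collapses to the index position
  prox$r2 <- c(0.89, 0.89)
  b <- build_ld_blocks(prox, snps)
  expect_equal(c(b$start, b$end), c(1000L, 1001L))

  expect_error(build_ld_blocks(
    data.frame(index_rsid = "rs999", proxy_rsid = "p", pos = 1L, r2 = 1),
    snps), "absent")
})

test_that("block extents equal a filter-then-extent oracle and shrink with r2", {
  set.seed(251)
  snps <- snp_cat(sort(sample.int(10000L, 8L)))
  prox <- do.call(rbind, lapply(snps$rsid, function(r) {
    k <- sample(3:7, 1)
    data.frame(index_rsid = r, proxy_rsid = paste0(r, "_", 1:k),
               pos = sample.int(10000L, k),
               r2 = round(runif(k, 0.5, 1), 3), stringsAsFactors = FALSE)
  }))
  for (r2min in c(0.7, 0.9, 0.95)) {
    b <- build_ld_blocks(prox, snps, r2_min = r2min)
    for (i in seq_len(nrow(snps))) {
      qual <- prox$pos[prox$index_rsid == snps$rsid[i] & prox$r2 >= r2min]
      expect_equal(b$start[i], min(c(snps$pos[i], qual)))
      expect_equal(b$end[i], max(c(snps$pos[i], qual)) + 1L)
    }
  }
  b_lo <- build_ld_blocks(prox, snps, r2_min = 0.7)
  b_hi <- build_ld_blocks(prox, snps, r2_min = 0.95)
  expect_true(all(b_hi$start >= b_lo$start))
  expect_true(all(b_hi$end <= b_lo$end))
})

test_that("miRNA/LD intersection matches a nested-loop oracle", {
  snps <- snp_cat(c(100L, 5000L))
  prox <- data.frame(index_rsid = c("rs001", "rs002"),
                     proxy_rsid = c("p1", "p2"),
                     pos = c(300L, 5600L), r2 = 0.95,
                     stringsAsFactors = FALSE)
  blocks <- build_ld_blocks(prox, snps)
  loci <- genomic_intervals("c", c(150L, 200L, 9000L),
                            c(180L, 320L, 9100L),
                            name = c("mA", "mB", "mC"))
  assoc <- intersect_mirna_ld(loci, blocks)
  expect_equal(sort(unique(assoc$mirna)), c("mA", "mB"))
  expect_equal(nrow(assoc), 2L)

  set.seed(261)
  loci <- genomic_intervals("c", s <- sample.int(9000L, 100L),
                            s + sample.int(200L, 100L, TRUE),
                            name = sprintf("m%03d", 1:100))
  want <- 0L
  for (i in 1:100) for (j in seq_len(nrow(blocks)))
    if (loci$start[i] < blocks$end[j] && loci$end[i] > blocks$start[j])
      want <- want + 1L
  expect_equal(nrow(intersect_mirna_ld(loci, blocks)), want)
})

test_that("disease summary deduplicates SNPs and normalized phenotypes", {
  snps <- snp_cat(c(100L, 200L), maf = 0.3,
                  phen = c("Diabetes; diabetes ;Asthma", "ASTHMA"))
  assoc <- data.frame(mirna = c("m1", "m1", "m2"),
                      index_rsid = c("rs001", "rs002", "rs001"),
                      stringsAsFactors = FALSE)
  s <- summarize_disease(assoc, snps)
  expect_equal(s$n_mirna_in_ld, 2L)
  expect_equal(s$n_unique_snps, 2L)
  expect_equal(s$n_unique_phenotypes, 2L) # diabetes + asthma, case-folded

  one <- summarize_disease(assoc[1, ], snps[1, ])
  expect_equal(one$n_unique_phenotypes, 2L)
  empty <- summarize_disease(assoc[0, ], snps)
  expect_equal(unlist(empty), c(n_mirna_in_ld = 0L, n_unique_snps = 0L,
                                n_unique_phenotypes = 0L))
  # row order never changes the summary
  s2 <- summarize_disease(assoc[c(3, 1, 2), ], snps[2:1, ])
  expect_equal(s, s2)
})

test_that("common-SNP overlap uses inclusive MAF and half-open position", {
  mir <- genomic_intervals("c", 100L, 122L, name = "m1")
  expect_true(common_snp_overlap(mir, snp_cat(100L, maf = 0.05), 0.05)[[1]])
  expect_false(common_snp_overlap(mir, snp_cat(100L, maf = 0.009), 0.01)[[1]])
  expect_false(common_snp_overlap(mir, snp_cat(122L, maf = 0.3), 0.01)[[1]])
  expect_true(common_snp_overlap(mir, snp_cat(121L, maf = 0.3), 0.01)[[1]])

  set.seed(271)
  mirs <- genomic_intervals("c", s <- sample.int(5000L, 40L), s + 22L,
                            name = sprintf("m%02d", 1:40))
  snps <- snp_cat(sample.int(5000L, 60L), maf = runif(60, 0, 0.5))
  for (cut in c(0.01, 0.05)) {
    flags <- common_snp_overlap(mirs, snps, cut)
    oracle <- vapply(seq_len(40), function(i)
      any(snps$pos >= mirs$start[i] & snps$pos < mirs$end[i] &
            snps$maf >= cut), logical(1))
    expect_equal(unname(flags), oracle, ignore_attr = TRUE)
  }
  # raising the MAF cutoff never flags more miRNAs
  expect_lte(attr(common_snp_overlap(mirs, snps, 0.05), "n_flagged"),
             attr(common_snp_overlap(mirs, snps, 0.01), "n_flagged"))
})
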