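test_that("read support equals a naive per-read oracle on generated FASTQ", {
  set.seed(221)
  mir <- c(mirX = random_dna(21, 0.5))
  cfg <- sim_config(seed = 9, n_datasets = 2L, n_decoys = 80L,
                    read_len = 36L)
  counts <- matrix(c(120L, 35L), nrow = 1,
                   dimnames = list("mirX", NULL))
  clip <- make_clip_reads(mir, counts = counts, config = cfg)
  sup <- count_read_support(mir[[1]], clip$paths, threshold = 100L)
  expect_equal(unname(sup$counts), c(120L, 35L))
  expect_equal(sup$total, 155L)
  expect_true(sup$supported)
  # oracle: naive scan over every read
  for (d in 1:2) {
    reads <- premirscan:::read_fastq_seqs(clip$paths[d])
    expect_equal(unname(sup$counts[d]), oracle_count_reads(mir[[1]], reads))
  }
})

test_that("a read equal to the miRNA itself is counted; absence gives zero", {
  mir <- strrep("ACGT", 5) # 20 nt
  expect_error(count_read_support("ACGTACGT", list("ACGTACGT")), "16 nt")
  sup <- count_read_support(mir, list(c(mir, random_dna(30, .5))),
                            threshold = 1L)
  expect_equal(sup$total, 1L)
  set.seed(231)
  rnd <- replicate(50, random_dna(36, .5))
  mir2 <- paste0(strrep("A", 10), strrep("C", 10)) # absent by construction
  expect_equal(count_read_support(mir2, list(rnd))$total, 0L)
})

test_that("the supporting-read threshold boundary is inclusive", {
  expect_false(flag_supported(499L))
  expect_true(flag_supported(500L))
  expect_false(flag_supported(integer(0)))
  expect_true(flag_supported(c(300L, 300L)))            # summed by default
  expect_false(flag_supported(c(300L, 300L), per_dataset = TRUE))
  expect_true(flag_supported(c(500L, 700L), per_dataset = TRUE))
})

test_that("adding reads never decreases a count", {
  set.seed(241)
  mir <- random_dna(20, 0.5)
  base <- c(replicate(20, random_dna(36, .5)),
            paste0(random_dna(8, .5), mir, random_dna(8, .5)))
  more <- c(base, paste0(mir, random_dna(16, .5)))
  expect_gte(count_read_support(mir, list(more))$total,
             count_read_support(mir, list(base))$total)
})

test_that("malformed FASTQ records are skipped with a warning", {
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGT", "+", strrep("I", 20),
               "not_a_header", "ACGT", "+", "II",
               "@r3", "ACGTACGTACGTACGTACGT", "+", strrep("I", 20)), tf)
  expect_warning(reads <- premirscan:::read_fastq_seqs(tf), "malformed")
  expect_equal(length(reads), 2L)
})

test_that("Dicer calls reproduce the pooled t-test and direction rule", {
  mk <- function(sil, ctl, target = "m1") {
    rbind(
      data.frame(sample = c("s1", "s2", "c1", "c2"),
                 condition = c("silenced", "silenced", "control", "control"),
                 target = "ACTB", ct = 15, stringsAsFactors = FALSE),
      data.frame(sample = c("s1", "s2", "c1", "c2"),
                 condition = c("silenced", "silenced", "control", "control"),
                 target = target, ct = 15 + c(sil, ctl),
                 stringsAsFactors = FALSE))
  }
  # planted attenuation: silenced delta-Ct {8.0, 8.2} vs control {5.0, 5.1}
  res <- dicer_dependence_test(mk(c(8.0, 8.2), c(5.0, 5.1)))
  expect_lt(res$p_value, 0.05)
  expect_true(res$dependent)
  expect_equal(res$p_value, oracle_pooled_t_p(c(8.0, 8.2), c(5.0, 5.1)),
               tolerance = 1e-12)
  expect_equal(res$ddct, mean(c(8.0, 8.2)) - mean(c(5.0, 5.1)))
  expect_equal(res$fold_change, 2^(-res$ddct))

  # identical measurements: no evidence, never dependent
  res0 <- dicer_dependence_test(mk(c(6, 6), c(6, 6)))
  expect_false(res0$dependent)

  # expression UP on silencing is not Dicer dependence regardless of p
  resr <- dicer_dependence_test(mk(c(5.0, 5.1), c(8.0, 8.2)))
  expect_lt(resr$p_value, 0.05)
  expect_false(resr$dependent)
})

test_that("Dicer test skips targets with missing normalizer", {
  tab <- data.frame(
    sample = c("s1", "s2", "c1", "c2", "s1", "s2", "c1", "c2", "x9"),
    condition = c(rep(c("silenced", "silenced", "control", "control"), 2),
                  "silenced"),
    target = c(rep("ACTB", 4), rep("m1", 4), "m2"),
    ct = c(rep(15, 4), 20, 21, 18, 18.5, 22), stringsAsFactors = FALSE)
  expect_warning(res <- dicer_dependence_test(tab), "m2")
  expect_equal(res$target, "m1")
  expect_error(dicer_dependence_test(tab, normalizer = "GAPDH"), "absent")
})
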