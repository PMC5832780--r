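test_that("window enumeration counts and strand handling are exact", {
  set.seed(81)
  s58 <- random_dna(58, 0.5)
  w <- enumerate_windows(s58, scan_config())
  expect_equal(nrow(w), 2L) # one window per strand
  expect_setequal(w$strand, c("-", "+"))

  s60 <- random_dna(60, 0.5)
  w <- enumerate_windows(s60, scan_config(min_len = 58, max_len = 60))
  expect_equal(nrow(w), 12L) # 2 * (3 + 2 + 1)

  # minus-strand window is the reverse complement of the forward slice
  minus <- w[w$start == 0 & w$end == 58 & w$strand == "-", ]
  expect_equal(minus$seq, revcomp(substr(s60, 1, 58)))
  plus <- w[w$start == 0 & w$end == 58 & w$strand == "+", ]
  expect_equal(plus$seq, substr(s60, 1, 58))

  expect_warning(enumerate_windows(random_dna(40, .5), scan_config()),
                 "shorter")
})

test_that("prescreen is a conservative pass/fail gate", {
  expect_false(prescreen(strrep("A", 60), threshold = 7))
  hp <- plant_hairpin(25, 6, seed = 5)$seq
  expect_true(prescreen(hp, threshold = 7))
  expect_true(all(prescreen(c(strrep("A", 60), hp), threshold = 0)))
})

test_that("disabling the prescreen never changes the scan result", {
  set.seed(91)
  hp <- plant_hairpin(22, 6)$seq
  seq <- paste0(random_dna(120, 0.41), hp, random_dna(120, 0.41))
  with_ps <- scan_sequence(seq, scan_config(prescreen = TRUE))
  without_ps <- scan_sequence(seq, scan_config(prescreen = FALSE))
  expect_equal(with_ps$start, without_ps$start)
  expect_equal(with_ps$mfe, without_ps$mfe)
  expect_equal(with_ps$structure, without_ps$structure)
})

test_that("scan recovers a planted hairpin and respects the MFE cutoff", {
  set.seed(101)
  hp <- plant_hairpin(25, 6)$seq
  seq <- paste0(random_dna(150, 0.41), hp, random_dna(150, 0.41))
  w <- scan_sequence(seq, scan_config(), chrom = "fix")
  expect_gt(nrow(w), 0L)
  expect_true(any(w$start < 150 + nchar(hp) & w$end > 150))
  expect_true(all(w$mfe < -20))
  expect_true(all(w$n_hairpin_loops == 1L))
  expect_true(all(w$n_bulges == 0L))
  expect_true(all(w$n_multiloops == 0L))
  counts <- attr(w, "stage_counts")
  expect_true(all(diff(counts) <= 0)) # funnel shrinks monotonically
})

test_that("the scan is invariant to input-strand orientation", {
  set.seed(111)
  hp <- plant_hairpin(22, 5)$seq
  seq <- paste0(random_dna(80, 0.41), hp, random_dna(80, 0.41))
  fwd <- scan_sequence(seq, scan_config())
  rev <- scan_sequence(revcomp(seq), scan_config())
  L <- nchar(seq)
  # same windows, with mirrored coordinates and flipped strand
  key_f <- sort(paste(fwd$start, fwd$end, fwd$strand))
  key_r <- sort(paste(L - rev$end, L - rev$start,
                      ifelse(rev$strand == "+", "-", "+")))
  expect_equal(key_f, key_r)
})

test_that("stride-1 windows are a superset of coarser strides", {
  set.seed(121)
  hp <- plant_hairpin(20, 6)$seq
  seq <- paste0(random_dna(60, 0.41), hp, random_dna(60, 0.41))
  w1 <- scan_sequence(seq, scan_config(stride = 1))
  w3 <- scan_sequence(seq, scan_config(stride = 3))
  key <- function(w) paste(w$start, w$end, w$strand)
  expect_true(all(key(w3) %in% key(w1)))
  expect_true(all(w3$start %% 3 == 0))
})

test_that("exon exclusion obeys half-open overlap semantics", {
  loci <- genomic_intervals("c", c(100, 100), c(160, 160),
                            name = c("a", "b"))
  expect_equal(nrow(exclude_exons(loci[1, ],
                                  genomic_intervals("c", 159, 200))), 0L)
  expect_equal(nrow(exclude_exons(loci[1, ],
                                  genomic_intervals("c", 160, 200))), 1L)
  set.seed(131)
  ls <- sample.int(500L, 200L, TRUE) - 1L
  le <- ls + sample.int(30L, 200L, TRUE)
  es <- sample.int(500L, 60L, TRUE) - 1L
  ee <- es + sample.int(30L, 60L, TRUE)
  loci <- genomic_intervals("c", ls, le)
  exons <- genomic_intervals("c", es, ee)
  got <- exclude_exons(loci, exons)
  keep_oracle <- !vapply(seq_along(ls), function(i)
    oracle_any_overlap(ls[i], le[i], es, ee), logical(1))
  expect_equal(nrow(got), sum(keep_oracle))
  expect_equal(got$start, ls[keep_oracle])
})

test_that("atlas construction merges windows and annotates them", {
  w <- data.frame(chrom = "c", start = c(10L, 30L), end = c(70L, 90L),
                  strand = c("+", "-"), mfe = c(-25, -22))
  at <- build_atlas(w)
  expect_equal(nrow(at), 1L)
  expect_equal(at$n_windows, 2L)
  expect_equal(at$best_mfe, -25)
  expect_equal(at$start, 10L)
  expect_equal(at$end, 90L)
  expect_equal(nrow(build_atlas(w[0, ])), 0L)
})

test_that("cutoff derivation reproduces the percentile procedure", {
  lens <- seq(40, 130, by = 1)
  mfes <- seq(-60, -10, length.out = 91)
  cut <- derive_cutoffs(lens, mfes)
  expect_equal(cut$min_len, as.integer(round(quantile(lens, .05))))
  expect_equal(cut$max_len, as.integer(round(quantile(lens, .95))))
  expect_equal(cut$mfe_cutoff, unname(quantile(mfes, .95)))
})

test_that("scan config validates and empty input scans empty", {
  expect_error(scan_config(min_len = 100, max_len = 60), "min_len")
  expect_error(scan_config(stride = 0), "stride")
  w <- suppressWarnings(scan_sequence(random_dna(10, .5), scan_config()))
  expect_equal(nrow(w), 0L)
})
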