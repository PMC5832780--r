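test_that("read_fasta normalizes case and alphabet and preserves order", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgu"), tf)
  expect_equal(read_fasta(tf), c(x = "ACGT"))

  writeLines(c(">a", "AC", ">b", "GT"), tf)
  expect_equal(names(read_fasta(tf)), c("a", "b"))

  # wrapped record equals the naive line-join
  set.seed(11)
  lines <- vapply(1:4, function(i) random_dna(30, 0.5), character(1))
  writeLines(c(">wrapped", lines), tf)
  expect_equal(unname(read_fasta(tf)["wrapped"]),
               paste(lines, collapse = ""))
  expect_equal(nchar(read_fasta(tf)[["wrapped"]]), 120L)
})

test_that("read_fasta rejects bad input with the offending record named", {
  tf <- withr::local_tempfile(fileext = ".fa")
  file.create(tf)
  expect_error(read_fasta(tf))
  writeLines(c(">a", "ACGT", ">a", "GGGG"), tf)
  expect_error(read_fasta(tf), "duplicate.*a")
  writeLines(c(">ok", "ACGT", ">bad", "ACXT"), tf)
  expect_error(read_fasta(tf), "bad")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("revcomp is correct, maps N to N, and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT") # palindrome
  expect_equal(revcomp("AAAC"), "GTTT")
  expect_equal(revcomp("ANT"), "ANT")
  expect_error(revcomp("ACXT"))
  set.seed(21)
  for (z in 1:100) {
    s <- random_dna(60, runif(1, 0.2, 0.8))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("merge_intervals matches a per-base mask oracle and is idempotent", {
  m <- merge_intervals(genomic_intervals(c("c", "c"), c(0, 50), c(100, 150)))
  expect_equal(m[, c("start", "end")],
               data.frame(start = 0L, end = 150L))
  expect_equal(nrow(merge_intervals(genomic_intervals(character(0),
                                                      integer(0),
                                                      integer(0)))), 0L)
  set.seed(31)
  starts <- sample.int(300L, 1000L, replace = TRUE) - 1L
  ends <- starts + sample.int(20L, 1000L, replace = TRUE)
  iv <- genomic_intervals("chr", starts, ends,
                          strand = sample(c("+", "-"), 1000, TRUE))
  got <- merge_intervals(iv)
  want <- oracle_mask_union(starts, ends, 400L)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # idempotent and order-independent
  expect_equal(merge_intervals(got)[, c("start", "end")],
               got[, c("start", "end")])
  perm <- iv[sample.int(nrow(iv)), ]
  expect_equal(merge_intervals(perm), got)
})

test_that("BED round trip preserves all six fields", {
  iv <- genomic_intervals(c("chr2", "chr1", "chr1"), c(5, 0, 10),
                          c(50, 8, 30), strand = c("+", "-", "+"),
                          name = c("w3", "w1", "w2"))
  iv$score <- c(3, 1, 2)
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, tf)
  back <- read_bed(tf)
  # writer sorts deterministically
  expect_equal(back$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(back$start, c(0L, 10L, 5L))
  expect_equal(back$name, c("w1", "w2", "w3"))
  expect_equal(back$strand, c("-", "+", "+"))
  # second round trip is a fixed point
  tf2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("genomic_intervals validates its invariants", {
  expect_error(genomic_intervals("c", -1, 5), "negative")
  expect_error(genomic_intervals("c", 5, 5), "half-open")
  expect_error(genomic_intervals("c", 0, 5, strand = "x"), "strand")
})

test_that("exon annotations are read from BED and GFF3", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(genomic_intervals("chr1", 10, 50, name = "exon1"), bed)
  expect_equal(read_exons(bed)$start, 10L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\t11\t50\t.\t+\t.\tParent=g1",
               "chr1\tsrc\texon\t61\t90\t.\t-\t.\tParent=g1"), gff)
  ex <- read_exons(gff)
  expect_equal(nrow(ex), 2L) # gene row dropped
  expect_equal(ex$start, c(10L, 60L)) # 1-based closed -> 0-based half-open
  expect_equal(ex$end, c(50L, 90L))
})
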