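test_that("reads with more than 30% low-quality bases are discarded", {
  expect_false(read_filter(c(rep(30, 69), rep(10, 31)))$keep)
  expect_true(read_filter(c(rep(30, 70), rep(10, 30)))$keep)  # strict >
  expect_true(read_filter(rep(30, 100))$keep)
})

test_that("low-quality read ends are trimmed, interior bases kept", {
  q <- c(10, 10, 10, rep(35, 93), 10, 10)
  r <- read_filter(q)
  expect_true(r$keep)
  expect_equal(r$from, 4L)
  expect_equal(r$to, 96L)
  # phred+33 string input is accepted
  r2 <- read_filter(intToUtf8(q + 33))
  expect_equal(r2, r)
})

test_that("missing base qualities follow the configured policy", {
  expect_warning(r <- read_filter("*"), "without base qualities")
  expect_false(r$keep)
  expect_true(read_filter("*", missing_quality = "keep")$keep)
})

test_that("pileup columns count high-quality exonic bases and conserve reads", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_tiny_bed(bed, list(c(10, 60), c(80, 130)))
  ts <- load_annotation(bed)
  # 15 reads of C over the first exon; 2 extra reads low-Q at one position
  reads <- c(
    replicate(15, list(pos1 = 21, seq = strrep("C", 20)), simplify = FALSE),
    replicate(2, list(pos1 = 21, seq = strrep("C", 20),
                      qual = paste0(strrep("I", 9), "+", strrep("I", 10))),
              simplify = FALSE),
    # intron-only read: contributes to no column
    list(list(pos1 = 61, seq = strrep("A", 15))))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_tiny_sam(reads, sam)
  p <- build_pileups(sam, ts)
  col <- p$pileup[pos == 29L]  # 0-based position of the low-Q base (SAM 30)
  expect_equal(col$C, 15L)
  expect_equal(col$other, 2L)
  other_col <- p$pileup[pos == 25L]
  expect_equal(other_col$C, 17L)
  expect_false(any(p$pileup$pos >= 60 & p$pileup$pos < 80))
  # conservation: every covered exonic position sums to the covering reads
  expect_true(all(p$pileup[, A + C + G + T + other] == 17L |
                    p$pileup[, A + C + G + T + other] == 15L))
  # intron-only read still counts as mapped for the library total
  expect_equal(unname(p$total_reads), 18)
})

test_that("trimmed read ends contribute nothing to the pileup", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_tiny_bed(bed, list(c(0, 100)))
  ts <- load_annotation(bed)
  sam <- withr::local_tempfile(fileext = ".sam")
  # Q<20 on the first 3 and last 2 bases only: kept, 5 positions excluded
  write_tiny_sam(list(list(pos1 = 11, seq = strrep("G", 20),
                           qual = paste0("+++", strrep("I", 15), "++"))),
                 sam)
  p <- build_pileups(sam, ts)
  expect_equal(nrow(p$pileup), 15L)
  expect_equal(range(p$pileup$pos), c(13L, 27L))
  expect_equal(sum(p$pileup$other), 0L)
})

test_that("alignments to unknown sequences are a hard error naming them", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_tiny_bed(bed, list(c(10, 60)))
  ts <- load_annotation(bed)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrX\tLN:1000",
               sprintf("r1\t0\tchrX\t11\t60\t10M\t*\t0\t0\t%s\t%s",
                       strrep("A", 10), strrep("I", 10))), sam)
  expect_error(build_pileups(sam, ts), "chrX")
})

test_that("replicate files are pooled and per-file totals retained", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_tiny_bed(bed, list(c(10, 60)))
  ts <- load_annotation(bed)
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  write_tiny_sam(replicate(6, list(pos1 = 21, seq = strrep("A", 10)),
                           simplify = FALSE), s1)
  write_tiny_sam(replicate(4, list(pos1 = 21, seq = strrep("A", 10)),
                           simplify = FALSE), s2)
  p <- build_pileups(c(s1, s2), ts)
  expect_equal(p$pileup[pos == 20L]$A, 10L)
  expect_equal(unname(p$total_reads), c(6, 4))
  expect_equal(p$read_counts$n_reads, 10L)
})
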