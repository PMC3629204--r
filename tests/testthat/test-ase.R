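test_that("the exact binomial bias test reproduces worked values", {
  expect_equal(binomial_bias_test(10, 10), 1)
  expect_equal(binomial_bias_test(20, 0), 2 * 0.5^20)
  # straddle the P < 0.01 significance gate
  p164 <- binomial_bias_test(16, 4)
  p173 <- binomial_bias_test(17, 3)
  expect_equal(p164, 2 * pbinom(4, 20, 0.5), tolerance = 1e-12)
  expect_equal(p173, 2 * pbinom(3, 20, 0.5), tolerance = 1e-12)
  expect_gt(p164, 0.01)
  expect_lt(p173, 0.01)
})

test_that("the bias test agrees with enumeration and binom.test", {
  for (n in c(1, 2, 3, 7, 20, 41, 60)) {
    k <- 0:n
    p <- binomial_bias_test(k, n - k)
    oracle <- vapply(k, enum_binom_p, numeric(1), n = n)
    expect_lt(max(abs(p - oracle)), 1e-12)
    bt <- vapply(k, function(kk) binom.test(kk, n)$p.value, numeric(1))
    expect_equal(p, bt, tolerance = 1e-12)
  }
  # symmetry
  expect_equal(binomial_bias_test(13, 37), binomial_bias_test(37, 13))
  expect_true(is.na(binomial_bias_test(0, 0)))
})

test_that("hybrid allele counting splits columns by parental allele", {
  snps <- data.table(transcript_id = "tx1", chrom = "chr1",
                     pos = c(100L, 200L), allele_p1 = "C", allele_p2 = "T",
                     depth_p1 = 30L, depth_p2 = 25L, qual = 40, stages = "both")
  pile <- make_pileup(list(`100` = c(C = 18, T = 12),
                           `200` = c(C = 10, T = 9, G = 1)))
  rec <- count_hybrid_alleles(pile, snps, "tillering")
  expect_equal(rec[pos == 100L, .(n_p1, n_p2, n_other)],
               data.table(n_p1 = 18L, n_p2 = 12L, n_other = 0L))
  expect_equal(rec[pos == 200L]$n_other, 1L)
  expect_equal(rec$stage, rep("tillering", 2))
})

test_that("transcripts under 20 SNP-supporting reads are discarded", {
  snps <- data.table(transcript_id = c("tx1", "tx2"), chrom = "chr1",
                     pos = c(100L, 300L), allele_p1 = "C", allele_p2 = "T",
                     depth_p1 = 30L, depth_p2 = 25L, qual = 40, stages = "both")
  pile <- rbind(make_pileup(list(`100` = c(C = 10, T = 9))),          # 19
                make_pileup(list(`300` = c(C = 10, T = 10)), "tx2"))  # 20
  rec <- count_hybrid_alleles(pile, snps, "heading")
  expect_equal(unique(rec$transcript_id), "tx2")
})

test_that("uncovered SNPs yield zero-count records excluded from testing", {
  snps <- data.table(transcript_id = "tx1", chrom = "chr1",
                     pos = c(100L, 200L), allele_p1 = "C", allele_p2 = "T",
                     depth_p1 = 30L, depth_p2 = 25L, qual = 40, stages = "both")
  pile <- make_pileup(list(`100` = c(C = 15, T = 10)))  # pos 200 uncovered
  rec <- count_hybrid_alleles(pile, snps, "tillering")
  expect_equal(rec[pos == 200L, n_p1 + n_p2 + n_other], 0L)
  expect_true(is.na(rec[pos == 200L]$p_value))
  calls <- aggregate_transcripts(rec)
  expect_equal(calls$n_snps, 1L)  # the zero-count record does not contribute
})

test_that("transcript aggregation follows the significance rules", {
  rec <- data.table(transcript_id = "tx1", stage = "tillering",
                    n_p1 = c(30L, 11L), n_p2 = c(10L, 9L),
                    p_value = c(0.004, 0.3),
                    p1_fraction = c(0.75, 0.55))
  expect_equal(aggregate_transcripts(rec)$direction, "p1_biased")
  rec2 <- copy(rec)[, `:=`(p_value = c(0.004, 0.004),
                           p1_fraction = c(0.75, 0.25),
                           n_p1 = c(30L, 10L), n_p2 = c(10L, 30L))]
  expect_equal(aggregate_transcripts(rec2)$direction, "contradictory")
  rec3 <- copy(rec)[, p_value := c(0.02, 0.3)]
  expect_equal(aggregate_transcripts(rec3)$direction, "balanced")
})

test_that("relabelling the parents flips directions, not p-values", {
  set.seed(4)
  rec <- data.table(transcript_id = rep(sprintf("t%d", 1:20), each = 2),
                    stage = "tillering",
                    n_p1 = rpois(40, 30), n_p2 = rpois(40, 15))
  rec[, p_value := binomial_bias_test(n_p1, n_p2)]
  rec[, p1_fraction := n_p1 / (n_p1 + n_p2)]
  swapped <- copy(rec)[, `:=`(n_p1 = n_p2, n_p2 = n_p1,
                              p_value = binomial_bias_test(n_p2, n_p1),
                              p1_fraction = n_p2 / (n_p1 + n_p2))]
  a <- aggregate_transcripts(rec)
  b <- aggregate_transcripts(swapped)
  expect_equal(a$min_p, b$min_p)
  flip <- c(p1_biased = "p2_biased", p2_biased = "p1_biased",
            balanced = "balanced", contradictory = "contradictory")
  expect_equal(unname(flip[a$direction]), b$direction)
  expect_equal(a$p1_fraction, 1 - b$p1_fraction)
})

test_that("lowering alpha never increases the number of biased transcripts", {
  set.seed(5)
  rec <- data.table(transcript_id = rep(sprintf("t%d", 1:50), each = 2),
                    stage = "tillering",
                    n_p1 = rpois(100, 40), n_p2 = rpois(100, 25))
  rec[, `:=`(p_value = binomial_bias_test(n_p1, n_p2),
             p1_fraction = n_p1 / (n_p1 + n_p2))]
  biased <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a)
    sum(aggregate_transcripts(rec, alpha = a)$direction %in%
          c("p1_biased", "p2_biased")), numeric(1))
  expect_true(all(diff(biased) <= 0))
})

test_that("stage patterns and strong-bias classes follow the cutoffs", {
  mk <- function(ft, fh, dt = "p1_biased", dh = "p1_biased")
    data.table(transcript_id = "tx1", stage = c("tillering", "heading"),
               n_snps = 2L, n_significant = 1L, direction = c(dt, dh),
               supporting_reads = 100L, p1_fraction = c(ft, fh),
               min_p = 0.001)
  p <- classify_stage_patterns(mk(0.75, 0.72))
  expect_equal(p$pattern, "both_stages")
  expect_equal(p$strong_bias, "p1_predominant")
  # boundary is strict: exactly 0.7 is not strong
  expect_equal(classify_stage_patterns(mk(0.7, 0.68))$strong_bias, "none")
  expect_equal(classify_stage_patterns(mk(0.75, 0.25, "p1_biased",
                                          "p2_biased"))$strong_bias,
               "switching")
  expect_equal(classify_stage_patterns(mk(0.6, 0.55, "p1_biased",
                                          "balanced"))$pattern,
               "tillering_only")
  expect_equal(classify_stage_patterns(mk(0.52, 0.5, "balanced",
                                          "balanced"))$pattern, "none")
})

test_that("the census partitions biased transcripts consistently", {
  set.seed(6)
  n <- 60
  calls <- data.table(
    transcript_id = rep(sprintf("t%02d", 1:n), each = 2),
    stage = rep(c("tillering", "heading"), n),
    n_snps = 2L, n_significant = 1L,
    direction = sample(c("p1_biased", "p2_biased", "balanced"), 2 * n,
                       replace = TRUE, prob = c(0.3, 0.2, 0.5)),
    supporting_reads = 100L,
    p1_fraction = runif(2 * n, 0.2, 0.8), min_p = 0.005)
  patterns <- classify_stage_patterns(calls)
  cen <- bias_census(patterns, calls)
  ct <- cen$counts
  expect_equal(ct$biased_any, ct$biased_both + ct$biased_one)
  per <- ct$per_stage
  expect_equal(per$biased, per$p1_biased + per$p2_biased)
  expect_equal(sum(patterns$pattern == "both_stages"), ct$biased_both)
})
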