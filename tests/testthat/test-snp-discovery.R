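test_that("consensus requires unanimity unless a minor fraction is allowed", {
  expect_equal(consensus_base(c(A = 0, C = 15, G = 0, T = 0)), "C")
  expect_true(is.na(consensus_base(c(A = 0, C = 14, G = 0, T = 1))))
  expect_equal(consensus_base(c(A = 0, C = 14, G = 0, T = 1), 0.1), "C")
  expect_true(is.na(consensus_base(c(A = 0, C = 0, G = 0, T = 0))))
})

test_that("site quality is monotone in depth and penalises discordance", {
  expect_gte(site_quality(10, 10), 20)            # unanimous at minimum depth
  expect_gte(site_quality(15, 15, 12, 12), 20)
  depths <- c(10, 20, 50, 100)
  q <- site_quality(depths, depths)
  expect_true(all(diff(q) > 0))
  expect_lt(site_quality(14, 15), site_quality(15, 15))
})

test_that("SNP calling applies consensus, depth, stage and quality criteria", {
  # clean inter-parental SNP at both stages
  p1 <- list(tillering = make_pileup(list(`100` = c(C = 15))),
             heading = make_pileup(list(`100` = c(C = 15))))
  p2 <- list(tillering = make_pileup(list(`100` = c(T = 12))),
             heading = make_pileup(list(`100` = c(T = 12))))
  s <- call_snps(p1, p2)
  expect_equal(nrow(s), 1L)
  expect_equal(s$allele_p1, "C")
  expect_equal(s$allele_p2, "T")
  expect_equal(s$depth_p1, 30L)  # summed over stages
  # depth 9 in one parent: no call
  p1$tillering <- make_pileup(list(`100` = c(C = 9)))
  expect_equal(nrow(call_snps(p1, p2)), 0L)
  # covered at one stage only: no call
  p1$tillering <- make_pileup(list(`100` = c(C = 15)))
  p2$heading <- make_pileup(list())
  expect_equal(nrow(call_snps(p1, p2)), 0L)
})

test_that("stage-discordant allele pairs are dropped with a message", {
  p1 <- list(tillering = make_pileup(list(`100` = c(C = 15))),
             heading = make_pileup(list(`100` = c(C = 15))))
  p2 <- list(tillering = make_pileup(list(`100` = c(T = 12))),
             heading = make_pileup(list(`100` = c(G = 12))))
  expect_message(s <- call_snps(p1, p2), "stage-discordant")
  expect_equal(nrow(s), 0L)
})

test_that("the 12-site fixture survives exactly as manual rule application", {
  fx <- filter_fixture()
  snps <- suppressMessages(
    call_snps(fx$p1, fx$p2, min_depth = 10, min_qual = 20,
              max_minor_fraction = 0.2))
  expect_setequal(snps$pos, fx$expected_pos)
})

test_that("raising the depth threshold never gains SNPs", {
  fx <- filter_fixture()
  n <- vapply(c(10, 12, 15, 25, 60), function(d)
    nrow(suppressMessages(call_snps(fx$p1, fx$p2, min_depth = d,
                                    max_minor_fraction = 0.2))),
    numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("substitution classes collapse with their strand complements", {
  cls <- substitution_class(c("C", "G", "A"), c("T", "A", "G"))
  expect_equal(as.character(cls), c("C>T", "C>T", "A>G"))
  sp <- substitution_spectrum(data.frame(allele_p1 = c("C", "G", "A"),
                                         allele_p2 = c("T", "A", "G")))
  expect_equal(unname(sp$class_counts[c("C>T", "A>G")]), c(2L, 1L))
  expect_equal(sp$ct_ga_fraction, 1)  # all three are transition types
})

test_that("spectrum counts are invariant under reverse-complementing alleles", {
  set.seed(99)
  pairs <- t(replicate(500, sample(c("A", "C", "G", "T"), 2)))
  sp1 <- substitution_spectrum(data.frame(allele_p1 = pairs[, 1],
                                          allele_p2 = pairs[, 2]))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sp2 <- substitution_spectrum(data.frame(allele_p1 = comp[pairs[, 1]],
                                          allele_p2 = comp[pairs[, 2]]))
  expect_equal(sp1$class_counts, sp2$class_counts)
})

test_that("a balanced directed spectrum gives a C:T/G:A share of one third", {
  # all 12 directed substitutions equally often: exactly 4/12 are transitions
  from <- rep(c("A", "A", "A", "C", "C", "C", "G", "G", "G", "T", "T", "T"),
              each = 100)
  to <- rep(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
            each = 100)
  sp <- substitution_spectrum(data.frame(allele_p1 = from, allele_p2 = to))
  expect_equal(sp$ct_ga_fraction, 1 / 3)
  expect_equal(sum(sp$class_counts), 1200L)
})

test_that("an empty SNP set yields a zero spectrum", {
  sp <- substitution_spectrum(data.frame(allele_p1 = character(),
                                         allele_p2 = character()))
  expect_equal(sum(sp$class_counts), 0L)
  expect_equal(sp$ct_ga_fraction, 0)
})
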