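test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_transcripts = 4, depth_mean = 60, seed = 21)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$snps, t2$snps)
  expect_identical(t1$transcript_truth, t2$transcript_truth)
  r1 <- simulate_reads(t1, "hybrid", "tillering", 1)
  r2 <- simulate_reads(t2, "hybrid", "tillering", 1)
  expect_identical(r1, r2)
  # replicates draw distinct read streams
  r3 <- simulate_reads(t1, "hybrid", "tillering", 2)
  expect_false(identical(r1$seq, r3$seq))
})

test_that("written datasets are byte-identical across runs", {
  cfg <- sim_config(n_transcripts = 3, depth_mean = 40, seed = 33)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  simulate_ase_dataset(cfg, d1)
  simulate_ase_dataset(cfg, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("transcript architecture honours the configuration", {
  cfg <- sim_config(n_transcripts = 10, exon_count_range = c(2, 2),
                    exon_length_range = c(200, 200), seed = 5)
  gen <- generate_genome_and_annotation(cfg)
  expect_equal(nrow(gen$transcripts$transcripts), 10L)
  expect_true(all(gen$transcripts$transcripts$summed_exon_length == 400L))
  expect_true(all(gen$transcripts$transcripts$n_exons == 2L))
})

test_that("planted SNPs land in exons with the requested spectrum", {
  cfg <- sim_config(n_transcripts = 20, snp_rate = 5, seed = 9,
                    spectrum_weights = c("A>C" = 0, "A>G" = 0, "A>T" = 0,
                                         "C>A" = 0, "C>G" = 0, "C>T" = 1))
  gen <- generate_genome_and_annotation(cfg)
  snps <- plant_snps(gen$transcripts, cfg)
  expect_gt(nrow(snps), 20)
  expect_true(all(snps$class == "C>T"))
  expect_true(all(paste(snps$allele_p1, snps$allele_p2) %in%
                    c("C T", "G A")))
  expect_false(any(duplicated(snps[, .(chrom, pos)])))
  # every planted SNP lies inside an exon of its transcript
  ex <- gen$transcripts$exons
  inside <- vapply(seq_len(nrow(snps)), function(i) {
    e <- ex[transcript_id == snps$transcript_id[i]]
    any(snps$pos[i] >= e$start & snps$pos[i] < e$end)
  }, logical(1))
  expect_true(all(inside))
  # zero rate plants nothing
  expect_equal(nrow(plant_snps(gen$transcripts, sim_config(snp_rate = 0))), 0L)
})

test_that("error-free parental reads match their haplotype exactly", {
  cfg <- sim_config(n_transcripts = 3, depth_mean = 50, snp_rate = 4,
                    base_error_rate = 0, low_q_frac = 0, frac_bad_reads = 0,
                    seed = 13)
  truth <- simulate_truth(cfg)
  hap1 <- asepipe:::apply_alleles(as.list(truth$genome), truth$snps,
                                  "allele_p1")
  reads <- simulate_reads(truth, "parent1", "tillering", 1)
  ok <- vapply(seq_len(nrow(reads)), function(i)
    substring(hap1[[reads$chrom[i]]], reads$pos1[i],
              reads$pos1[i] + nchar(reads$seq[i]) - 1L) == reads$seq[i],
    logical(1))
  expect_true(all(ok))
})

test_that("hybrid allele fractions concentrate around the planted truth", {
  cfg <- sim_config(n_transcripts = 2, exon_count_range = c(1, 1),
                    exon_length_range = c(300, 300), depth_mean = 4000,
                    snp_rate = 6, base_error_rate = 0, low_q_frac = 0,
                    frac_bad_reads = 0, depth_sdlog = 0, seed = 17)
  truth <- simulate_truth(cfg)
  # force known fractions: transcript 1 fully parent-1, transcript 2 balanced
  truth$transcript_truth[, `:=`(f_tillering = c(1, 0.5), f_heading = c(1, 0.5))]
  reads <- simulate_reads(truth, "hybrid", "tillering", 1)
  ts <- truth$transcripts
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, truth$genome, sam)
  gff <- withr::local_tempfile(fileext = ".gff3")
  asepipe:::write_annotation_gff3(ts, gff)
  pile <- build_pileups(sam, load_annotation(gff))
  rec <- count_hybrid_alleles(pile, truth$snps, "tillering", min_support = 1)
  f1 <- rec[transcript_id == "tx0001"]
  expect_true(all(f1$n_p2 == 0))                  # degenerate fraction 1.0
  f2 <- rec[transcript_id == "tx0002" & n_p1 + n_p2 > 500]
  expect_true(all(abs(f2$p1_fraction - 0.5) < 0.05))  # ~3 sigma at depth 1000+
})
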