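# Shared fixture builders. Everything is generated in code at test time.

library(data.table)

# a pileup table row set from compact specs: list(pos = c(A=..,C=..,...))
make_pileup <- function(spec, transcript_id = "tx1", chrom = "chr1") {
  if (!length(spec))
    return(data.table(transcript_id = character(), chrom = character(),
                      pos = integer(), A = integer(), C = integer(),
                      G = integer(), T = integer(), other = integer()))
  rows <- lapply(names(spec), function(p) {
    cnt <- spec[[p]]
    dt <- data.table(transcript_id = transcript_id, chrom = chrom,
                     pos = as.integer(p), A = 0L, C = 0L, G = 0L, T = 0L,
                     other = 0L)
    for (b in names(cnt)) dt[[b]] <- as.integer(cnt[[b]])
    dt
  })
  rbindlist(rows)
}

# hand-written SAM: reads as list(pos1=, seq=, qual=) on a tiny reference
write_tiny_sam <- function(reads, path, chrom = "chr1", chrom_len = 1000L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    cigar <- if (is.null(r$cigar)) paste0(nchar(r$seq), "M") else r$cigar
    qual <- if (is.null(r$qual)) strrep("I", nchar(r$seq)) else r$qual
    flag <- if (is.null(r$flag)) 0L else r$flag
    ch <- if (is.null(r$chrom)) chrom else r$chrom
    sprintf("r%03d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            i, flag, ch, r$pos1, cigar, r$seq, qual)
  }, character(1L))
  writeLines(c(hdr, body), path)
  path
}

# BED12 annotation with one transcript: exons as 0-based half-open intervals
write_tiny_bed <- function(path, exons, name = "tx1", chrom = "chr1") {
  starts <- vapply(exons, `[[`, numeric(1), 1L)
  ends <- vapply(exons, `[[`, numeric(1), 2L)
  line <- sprintf("%s\t%d\t%d\t%s\t0\t+\t%d\t%d\t0\t%d\t%s\t%s",
                  chrom, min(starts), max(ends), name, min(starts),
                  max(ends), length(exons),
                  paste0(paste(ends - starts, collapse = ","), ","),
                  paste0(paste(starts - min(starts), collapse = ","), ","))
  writeLines(line, path)
  path
}

# The 12-site parental pileup fixture exercising every SNP-calling rule,
# used with max_minor_fraction = 0.2. Expected survivors (manual application
# of the rules, recorded in test-snp-discovery): sites 1, 3, 4, 10, 12.
filter_fixture <- function() {
  # per site: p1/p2 counts at tillering and heading (identical unless noted)
  both <- function(p1, p2) list(t = list(p1 = p1, p2 = p2),
                                h = list(p1 = p1, p2 = p2))
  sites <- list(
    both(c(C = 15), c(T = 12)),                 # 1: clean call
    both(c(C = 9),  c(T = 12)),                 # 2: parent-1 depth 9 < 10
    both(c(C = 10), c(T = 10)),                 # 3: exact depth boundary
    both(c(C = 14, T = 1), c(T = 12)),          # 4: tolerated minor read
    both(c(C = 11, T = 4), c(T = 12)),          # 5: no consensus (4/15 > 0.2)
    list(t = list(p1 = c(C = 15), p2 = NULL),   # 6: parent 2 uncovered
         h = list(p1 = c(C = 15), p2 = NULL)),
    list(t = list(p1 = c(C = 15), p2 = c(T = 12)),  # 7: tillering only
         h = list(p1 = NULL, p2 = NULL)),
    list(t = list(p1 = c(C = 15), p2 = c(T = 12)),  # 8: stage-discordant
         h = list(p1 = c(C = 15), p2 = c(G = 12))),
    both(c(C = 15), c(C = 12)),                 # 9: identical consensus
    both(c(C = 50), c(T = 40)),                 # 10: deep clean call
    both(c(C = 20), c(T = 11, C = 2)),          # 11: site quality 19.5 < 20
    both(c(C = 12), c(T = 10, C = 1))           # 12: quality 22.3 passes
  )
  piles <- list(p1 = list(tillering = list(), heading = list()),
                p2 = list(tillering = list(), heading = list()))
  add <- function(role, stage, pos, cnt) {
    if (is.null(cnt)) return()
    piles[[role]][[stage]][[as.character(pos)]] <<- cnt
  }
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    add("p1", "tillering", i * 10L, s$t$p1)
    add("p2", "tillering", i * 10L, s$t$p2)
    add("p1", "heading", i * 10L, s$h$p1)
    add("p2", "heading", i * 10L, s$h$p2)
  }
  list(p1 = lapply(piles$p1, make_pileup), p2 = lapply(piles$p2, make_pileup),
       expected_pos = c(1L, 3L, 4L, 10L, 12L) * 10L)
}

# independent brute-force oracle for the two-sided minimum-likelihood
# binomial p-value, from first principles via choose()
enum_binom_p <- function(k, n) {
  pk <- choose(n, 0:n) * 0.5^n
  sum(pk[pk <= pk[k + 1L] * (1 + 1e-7)])
}

# one small end-to-end dataset shared across test files (built on first use)
.e2e_cache <- new.env(parent = emptyenv())
e2e_fixture <- function() {
  if (is.null(.e2e_cache$ds)) {
    cfg <- sim_config(n_transcripts = 12, depth_mean = 250,
                      exon_count_range = c(2, 4),
                      exon_length_range = c(200, 400),
                      base_error_rate = 0, snp_rate = 3, seed = 11)
    dir <- file.path(tempdir(), "asepipe-e2e")
    ds <- simulate_ase_dataset(cfg, dir)
    pc <- pipeline_config(ds$annotation, ds$sam,
                          out_dir = file.path(dir, "out"))
    .e2e_cache$ds <- ds
    .e2e_cache$run <- run_pipeline(pc)
    .e2e_cache$config <- pc
  }
  list(ds = .e2e_cache$ds, run = .e2e_cache$run, config = .e2e_cache$config)
}
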