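#' Simulation configuration for synthetic hybrid RNA-seq data
#'
#' Defines the statistical structure of a synthetic dataset: transcript
#' architecture, inter-parental SNP density and substitution spectrum,
#' sequencing depth and error, and the planted allele-specific expression
#' structure (which transcripts are biased, how strongly, at which stages,
#' and whether the bias is mirrored in the parents as a cis effect).
#'
#' Defaults emulate the structure of a two-parent/one-hybrid rice root
#' RNA-seq experiment at two developmental stages: 100 bp reads, two pooled
#' biological replicates per condition, a substitution spectrum in which
#' C<->T / G<->A changes carry 68% of the mass (methylcytosine-deamination
#' enrichment), about 17% of transcripts with a planted allelic bias of
#' which roughly a quarter are biased at both stages, about two thirds of
#' biases favouring parent 1, a small strongly biased minority
#' (fraction < 0.3 or > 0.7) and a rare stage-switching class.
#'
#' @param n_transcripts Number of transcripts.
#' @param exon_count_range,exon_length_range,intron_length_range Integer
#'   ranges (bases) for transcript architecture.
#' @param snp_rate Expected planted SNPs per exonic kilobase.
#' @param spectrum_weights Named probabilities over [SPECTRUM_CLASSES];
#'   default puts 0.52 on C>T and 0.16 on A>G (transitions sum to 0.68) and
#'   0.08 on each remaining class.
#' @param depth_mean,depth_sdlog Reads per transcript per library:
#'   lognormal transcript-level factor (sdlog) around `depth_mean`.
#' @param read_length Read length in bases (default 100).
#' @param base_error_rate Per-base miscall probability (miscalls keep high
#'   quality scores, as real miscalls do).
#' @param low_q_frac Fraction of bases assigned quality below 20, to
#'   exercise base-quality filtering.
#' @param frac_bad_reads Fraction of reads with 40% low-quality bases, which
#'   the read-level filter should discard.
#' @param frac_biased Fraction of transcripts with a planted hybrid allelic
#'   bias (default 0.17).
#' @param p1_share Probability that a planted bias favours parent 1
#'   (default 0.67).
#' @param strong_frac Among biased transcripts, probability of drawing a
#'   strong fraction (> 0.7 before orientation; default 0.25).
#' @param frac_stage_both,frac_switching Among biased transcripts, the
#'   probability of bias at both stages (default 0.26) and of opposite-
#'   direction bias at the two stages (default 0.01); the rest are biased at
#'   one stage only.
#' @param cis_share Among biased transcripts, the probability that the bias
#'   is a pure cis effect: the parental expression ratio is set equal to the
#'   hybrid allelic ratio (default 0.3). Other biased transcripts have
#'   equal parental expression (allelic bias only).
#' @param frac_trans Among unbiased transcripts, the probability of a pure
#'   trans effect: parents differ by `de_log2fc` but hybrid alleles are
#'   balanced (default 0.08).
#' @param de_log2fc Magnitude of the planted parental log2 fold change for
#'   trans transcripts (default 1.5).
#' @param n_replicates Biological replicates per condition (default 2).
#' @param seed Integer seed; every generator operation derives its stream
#'   from it, so a dataset is fully reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 40,
                       exon_count_range = c(2, 6),
                       exon_length_range = c(150, 500),
                       intron_length_range = c(60, 200),
                       snp_rate = 2,
                       spectrum_weights = c("A>C" = 0.08, "A>G" = 0.16,
                                            "A>T" = 0.08, "C>A" = 0.08,
                                            "C>G" = 0.08, "C>T" = 0.52),
                       depth_mean = 300, depth_sdlog = 0.4,
                       read_length = 100,
                       base_error_rate = 0.001,
                       low_q_frac = 0.02, frac_bad_reads = 0.01,
                       frac_biased = 0.17, p1_share = 0.67,
                       strong_frac = 0.25,
                       frac_stage_both = 0.26, frac_switching = 0.01,
                       cis_share = 0.3, frac_trans = 0.08,
                       de_log2fc = 1.5,
                       n_replicates = 2, seed = 1) {
  spectrum_weights <- spectrum_weights[SPECTRUM_CLASSES]
  if (anyNA(spectrum_weights))
    stop("spectrum_weights must be named over: ",
         paste(SPECTRUM_CLASSES, collapse = ", "))
  if (abs(sum(spectrum_weights) - 1) > 1e-8)
    stop("spectrum_weights must sum to 1")
  props <- c(frac_biased = frac_biased, p1_share = p1_share,
             strong_frac = strong_frac, frac_stage_both = frac_stage_both,
             frac_switching = frac_switching, cis_share = cis_share,
             frac_trans = frac_trans, low_q_frac = low_q_frac,
             frac_bad_reads = frac_bad_reads,
             base_error_rate = base_error_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  rm(props)
  structure(as.list(environment()), class = "sim_config")
}

# derived sub-seed per generator operation, kept below 2^31
sim_seed <- function(config, offset) (config$seed %% 100000L) * 1000L + offset

# uniform integer draw on [range[1], range[2]], safe for degenerate ranges
sample_range <- function(range, n) {
  range[1L] + sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) - 1L
}

random_chrom_seq <- function(len) {
  paste(sample(NUCS, len, replace = TRUE), collapse = "")
}

#' Generate a reference genome and transcript annotation
#'
#' Lays `n_transcripts` multi-exon transcripts sequentially along synthetic
#' chromosomes (up to 25 per chromosome, 100 bp intergenic gaps) over a
#' random nucleotide background. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector of chromosome
#'   sequences) and `transcripts` (a `transcript_set`).
#' @export
generate_genome_and_annotation <- function(config) {
  set.seed(sim_seed(config, 1L))
  n <- config$n_transcripts
  exr <- config$exon_count_range; elr <- config$exon_length_range
  ilr <- config$intron_length_range
  rows <- vector("list", n)
  chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% 25L + 1L)
  cursor <- integer()
  for (i in seq_len(n)) {
    chrom <- chrom_of[i]
    at <- if (is.na(cursor[chrom])) 100L else cursor[chrom]
    k <- sample_range(exr, 1L)
    lens <- sample_range(elr, k)
    introns <- if (k > 1L) sample_range(ilr, k - 1L) else integer()
    starts <- at + cumsum(c(0L, lens[-k] + introns))
    rows[[i]] <- data.table::data.table(
      transcript_id = sprintf("tx%04d", i), chrom = chrom,
      start = starts, end = starts + lens,
      strand = sample(c("+", "-"), 1L))
    cursor[chrom] <- starts[k] + lens[k] + 100L
  }
  ex <- data.table::rbindlist(rows)
  genome <- vapply(split(ex$end, ex$chrom)[unique(chrom_of)],
                   function(e) random_chrom_seq(max(e) + 100L),
                   character(1L))
  list(genome = genome, transcripts = new_transcript_set(ex))
}

#' Plant inter-parental SNPs
#'
#' Draws per-transcript SNP counts as Poisson with mean `snp_rate` per
#' exonic kilobase, places them at distinct exonic positions, assigns each a
#' substitution class from `spectrum_weights`, and orients the class on the
#' genome strand at random (a C>T-class SNP is written as C/T or G/A with
#' equal probability). The parent-1 allele defines the reference frame.
#'
#' @param transcripts A `transcript_set`.
#' @param config A [sim_config()].
#' @return data.table of planted SNPs: `transcript_id`, `chrom`, `pos`
#'   (0-based genomic), `allele_p1`, `allele_p2`, `class`.
#' @export
plant_snps <- function(transcripts, config) {
  set.seed(sim_seed(config, 2L))
  ex <- transcripts$exons
  per_tx <- lapply(split(ex, by = "transcript_id"), function(e) {
    len <- sum(e$end - e$start)
    n <- min(rpois(1L, config$snp_rate * len / 1000), len)
    if (!n) return(NULL)
    exonic <- unlist(Map(function(s, t) s:(t - 1L), e$start, e$end))
    data.table::data.table(transcript_id = e$transcript_id[1L],
                           chrom = e$chrom[1L],
                           pos = sort(sample(exonic, n)))
  })
  snps <- data.table::rbindlist(per_tx)
  if (!nrow(snps))
    return(data.table::data.table(transcript_id = character(),
                                  chrom = character(), pos = integer(),
                                  allele_p1 = character(),
                                  allele_p2 = character(),
                                  class = character()))
  cls <- sample(SPECTRUM_CLASSES, nrow(snps), replace = TRUE,
                prob = config$spectrum_weights)
  a1 <- substr(cls, 1L, 1L)
  a2 <- substr(cls, 3L, 3L)
  flip <- runif(nrow(snps)) < 0.5
  snps[, allele_p1 := ifelse(flip, COMPLEMENT[a1], a1)]
  snps[, allele_p2 := ifelse(flip, COMPLEMENT[a2], a2)]
  snps[, class := cls]
  snps[]
}

# sampler for planted parent-1 fractions of biased transcripts
planted_fraction <- function(n, config) {
  mag <- ifelse(runif(n) < config$strong_frac,
                runif(n, 0.72, 0.92), runif(n, 0.56, 0.70))
  ifelse(runif(n) < config$p1_share, mag, 1 - mag)
}

#' Plant per-transcript expression and allelic-bias truth
#'
#' Assigns every transcript a regulatory mode and the resulting parental
#' log2 fold change and stage-wise hybrid parent-1 fractions:
#' \describe{
#'   \item{cis}{biased in the hybrid, with the parental expression ratio set
#'     equal to the planted allelic ratio (both stages).}
#'   \item{ase_only}{biased in the hybrid with equal parental expression;
#'     may be biased at both stages, one stage, or switch direction.}
#'   \item{trans}{parents differ by `de_log2fc`; hybrid alleles balanced.}
#'   \item{conserved}{no planted difference anywhere.}
#' }
#'
#' @param transcripts A `transcript_set`.
#' @param config A [sim_config()].
#' @return data.table: `transcript_id`, `reg_mode`, `lfc`, `f_tillering`,
#'   `f_heading`, `biased`, `depth_factor`.
#' @export
plant_transcript_truth <- function(transcripts, config) {
  set.seed(sim_seed(config, 3L))
  tx <- transcripts$transcripts$transcript_id
  n <- length(tx)
  biased <- runif(n) < config$frac_biased
  mode <- ifelse(biased,
                 ifelse(runif(n) < config$cis_share, "cis", "ase_only"),
                 ifelse(runif(n) < config$frac_trans, "trans", "conserved"))
  f <- planted_fraction(n, config)
  ft <- fh <- rep(0.5, n)
  lfc <- numeric(n)
  u <- runif(n)
  for (i in seq_len(n)) {
    if (mode[i] == "cis") {
      ft[i] <- fh[i] <- f[i]
      lfc[i] <- log2(f[i] / (1 - f[i]))
    } else if (mode[i] == "ase_only") {
      if (u[i] < config$frac_switching) {
        ft[i] <- f[i]; fh[i] <- 1 - f[i]
      } else if (u[i] < config$frac_switching + config$frac_stage_both) {
        ft[i] <- fh[i] <- f[i]
      } else if (u[i] < config$frac_switching + config$frac_stage_both +
                 (1 - config$frac_switching - config$frac_stage_both) / 2) {
        ft[i] <- f[i]
      } else {
        fh[i] <- f[i]
      }
    } else if (mode[i] == "trans") {
      lfc[i] <- config$de_log2fc * (if (runif(1) < config$p1_share) 1 else -1)
    }
  }
  data.table::data.table(transcript_id = tx, reg_mode = mode, lfc = lfc,
                         f_tillering = ft, f_heading = fh, biased = biased,
                         depth_factor = rlnorm(n, 0, config$depth_sdlog))
}

#' Simulate the full ground truth for one dataset
#'
#' Composes [generate_genome_and_annotation()], [plant_snps()] and
#' [plant_transcript_truth()] into one deterministic truth object.
#'
#' @param config A [sim_config()].
#' @return List of class `ase_truth`: `genome`, `transcripts`, `snps`,
#'   `transcript_truth`, `config`.
#' @export
simulate_truth <- function(config) {
  gen <- generate_genome_and_annotation(config)
  list(genome = gen$genome, transcripts = gen$transcripts,
       snps = plant_snps(gen$transcripts, config),
       transcript_truth = plant_transcript_truth(gen$transcripts, config),
       config = config) |>
    structure(class = "ase_truth")
}

# substitute single-base alleles into chromosome sequences
apply_alleles <- function(genome, snps, allele_col) {
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    seqv <- strsplit(genome[[ch]], "", fixed = TRUE)[[1L]]
    seqv[s$pos + 1L] <- s[[allele_col]]
    genome[[ch]] <- paste(seqv, collapse = "")
  }
  genome
}

sample_role_offset <- function(role, stage, replicate) {
  10L + 30L * match(role, c("parent1", "parent2", "hybrid")) +
    10L * match(stage, ASE_STAGES) + replicate
}

#' Simulate aligned reads for one library
#'
#' Draws reads uniformly within single exons of each transcript (reads do
#' not span splice junctions; alignment itself is out of scope, so records
#' are emitted already placed, with simple `<len>M` CIGARs). Parental reads
#' carry that parent's haplotype at every planted SNP; hybrid reads carry
#' the parent-1 haplotype with the transcript's stage-specific planted
#' fraction. Per-base miscalls are applied at `base_error_rate` (retaining
#' high quality scores); `low_q_frac` of bases get quality 10 and
#' `frac_bad_reads` of reads get 40% low-quality bases so that read- and
#' base-level quality filters are exercised.
#'
#' @param truth An `ase_truth` from [simulate_truth()].
#' @param role `"parent1"`, `"parent2"` or `"hybrid"`.
#' @param stage `"tillering"` or `"heading"`.
#' @param replicate Replicate index (its own read stream).
#' @return data.table of SAM fields (`qname`, `flag`, `chrom`, `pos1`,
#'   `mapq`, `cigar`, `seq`, `qual`).
#' @export
simulate_reads <- function(truth, role = c("parent1", "parent2", "hybrid"),
                           stage = ASE_STAGES, replicate = 1) {
  role <- match.arg(role)
  stage <- match.arg(stage)
  config <- truth$config
  set.seed(sim_seed(config, sample_role_offset(role, stage, replicate)))
  hap1 <- apply_alleles(as.list(truth$genome), truth$snps, "allele_p1")
  hap2 <- apply_alleles(as.list(truth$genome), truth$snps, "allele_p2")
  tt <- truth$transcript_truth
  exl <- split(truth$transcripts$exons, by = "transcript_id")
  fcol <- paste0("f_", stage)
  out <- vector("list", nrow(tt))
  rl <- config$read_length
  for (i in seq_len(nrow(tt))) {
    id <- tt$transcript_id[i]
    mult <- switch(role,
                   parent1 = 2^(tt$lfc[i] / 2),
                   parent2 = 2^(-tt$lfc[i] / 2),
                   hybrid = 1)
    n <- rpois(1L, tt$depth_factor[i] * config$depth_mean * mult)
    if (!n) next
    ex <- exl[[id]]
    wlen <- pmin(rl, ex$end - ex$start)
    npos <- ex$end - ex$start - wlen + 1L
    exi <- sample.int(nrow(ex), n, replace = TRUE, prob = npos)
    offs <- floor(runif(n) * npos[exi])
    start0 <- ex$start[exi] + as.integer(offs)
    len <- wlen[exi]
    use_p1 <- if (role == "parent1") rep(TRUE, n)
      else if (role == "parent2") rep(FALSE, n)
      else runif(n) < tt[[fcol]][i]
    chrom <- ex$chrom[1L]
    hapstr <- ifelse(use_p1, hap1[[chrom]], hap2[[chrom]])
    seqs <- substring(hapstr, start0 + 1L, start0 + len)
    out[[i]] <- data.table::data.table(
      transcript_id = id, chrom = chrom, pos1 = start0 + 1L, len = len,
      seq = seqs)
  }
  reads <- data.table::rbindlist(out)
  if (!nrow(reads))
    return(data.table::data.table(qname = character(), flag = integer(),
                                  chrom = character(), pos1 = integer(),
                                  mapq = integer(), cigar = character(),
                                  seq = character(), qual = character()))
  # per-base miscalls (quality stays high: miscalls look confident)
  nb <- sum(reads$len)
  n_err <- rbinom(1L, nb, config$base_error_rate)
  if (n_err > 0L) {
    flat <- sample.int(nb, n_err)
    ends <- cumsum(reads$len)
    rid <- findInterval(flat - 1L, ends) + 1L
    posin <- flat - c(0L, ends)[rid]
    for (j in seq_len(n_err)) {
      old <- substr(reads$seq[rid[j]], posin[j], posin[j])
      substr(reads$seq[rid[j]], posin[j], posin[j]) <-
        sample(setdiff(NUCS, old), 1L)
    }
  }
  # quality strings: Q40 baseline, sparse Q10 bases, a few bad reads
  quals <- vapply(reads$len, function(l)
    paste(rep.int("I", l), collapse = ""), character(1L))
  bad <- runif(nrow(reads)) < config$frac_bad_reads
  lowq_n <- rbinom(nrow(reads), reads$len,
                   ifelse(bad, 0.4, config$low_q_frac))
  for (j in which(lowq_n > 0L)) {
    at <- sample.int(reads$len[j], lowq_n[j])
    for (p in at) substr(quals[j], p, p) <- "+"
  }
  data.table::data.table(
    qname = sprintf("%s_%s_r%d_%06d", substr(role, 1, 4), substr(stage, 1, 4),
                    replicate, seq_len(nrow(reads))),
    flag = 0L, chrom = reads$chrom, pos1 = reads$pos1, mapq = 60L,
    cigar = paste0(reads$len, "M"), seq = reads$seq, qual = quals)
}

#' Write simulated reads as a SAM file
#'
#' @param reads data.table from [simulate_reads()].
#' @param genome Named character vector of chromosome sequences (for `@SQ`
#'   header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  reads <- reads[order(reads$chrom, reads$pos1), ]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos1,
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# write the annotation as GFF3 through rtracklayer
write_annotation_gff3 <- function(transcripts, path) {
  ex <- transcripts$exons
  tx <- transcripts$transcripts
  txgr <- GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(
      start = vapply(split(ex$start, ex$transcript_id)[tx$transcript_id],
                     min, numeric(1L)) + 1L,
      end = vapply(split(ex$end, ex$transcript_id)[tx$transcript_id],
                   max, numeric(1L))),
    strand = tx$strand)
  S4Vectors::mcols(txgr)$type <- "mRNA"
  S4Vectors::mcols(txgr)$ID <- tx$transcript_id
  S4Vectors::mcols(txgr)$Parent <- NA_character_
  exgr <- GenomicRanges::GRanges(ex$chrom,
                                 IRanges::IRanges(ex$start + 1L, ex$end),
                                 strand = ex$strand)
  S4Vectors::mcols(exgr)$type <- "exon"
  S4Vectors::mcols(exgr)$ID <- NA_character_
  S4Vectors::mcols(exgr)$Parent <- ex$transcript_id
  rtracklayer::export(c(txgr, exgr), path, format = "gff3")
  invisible(path)
}

#' Simulate and write a complete synthetic dataset
#'
#' Generates the truth for `config`, then writes to `dir`: the reference
#' FASTA (parent-1 frame), the GFF3 annotation, one SAM file per
#' role/stage/replicate, and the ground-truth tables as TSV.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List: `truth`, `annotation`, `genome_fa`, `truth_files`, and
#'   `sam` — a nested list `sam[[role]][[stage]]` of replicate file paths,
#'   directly usable by [pipeline_config()].
#' @export
simulate_ase_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(config)
  ref <- apply_alleles(as.list(truth$genome), truth$snps, "allele_p1")
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(ref)), fa)
  gff <- file.path(dir, "annotation.gff3")
  write_annotation_gff3(truth$transcripts, gff)
  roles <- c("parent1", "parent2", "hybrid")
  sam <- lapply(stats::setNames(roles, roles), function(role)
    lapply(stats::setNames(ASE_STAGES, ASE_STAGES), function(stage)
      vapply(seq_len(config$n_replicates), function(r) {
        p <- file.path(dir, sprintf("%s_%s_rep%d.sam", role, stage, r))
        write_sam(simulate_reads(truth, role, stage, r), truth$genome, p)
        p
      }, character(1L))))
  tf <- c(snps = file.path(dir, "truth_snps.tsv"),
          transcripts = file.path(dir, "truth_transcripts.tsv"))
  data.table::fwrite(truth$snps, tf[["snps"]], sep = "\t")
  data.table::fwrite(truth$transcript_truth, tf[["transcripts"]], sep = "\t")
  list(truth = truth, annotation = gff, genome_fa = fa, truth_files = tf,
       sam = sam, dir = dir)
}

#' Simulate count-level ASE data with planted regulatory modes
#'
#' A fast, read-free companion to the read simulator for statistical checks
#' of the cis/trans classifier: per transcript it draws pooled parental read
#' counts and hybrid allele counts directly. Modes: `cis` (parents differ by
#' `de_log2fc`, hybrid fraction matches the parental share), `trans`
#' (parents differ, hybrid balanced), `conserved` (no differences).
#'
#' @param n_transcripts Number of transcripts.
#' @param mode_probs Named probabilities over `c(cis, trans, conserved)`.
#' @param parent_depth Mean parental read count per transcript.
#' @param hybrid_depth Mean hybrid allele-informative depth per transcript.
#' @param de_log2fc Planted parental log2 fold change magnitude.
#' @param library_size Library size used for the Fisher test margins.
#' @param exon_length Summed exon length assigned to every transcript.
#' @param seed Integer seed.
#' @return data.table: `transcript_id`, `true_mode`, `lfc`, `f_true`,
#'   `count_p1`, `count_p2`, `n_p1`, `n_p2`, with attributes `library_size`
#'   and `exon_length`.
#' @export
simulate_ase_counts <- function(n_transcripts = 300,
                                mode_probs = c(cis = 1/3, trans = 1/3,
                                               conserved = 1/3),
                                parent_depth = 1000, hybrid_depth = 200,
                                de_log2fc = 1.5, library_size = 1e6,
                                exon_length = 1000, seed = 1) {
  set.seed(seed)
  mode <- sample(names(mode_probs), n_transcripts, replace = TRUE,
                 prob = mode_probs)
  lfc <- ifelse(mode == "conserved", 0,
                de_log2fc * sign(runif(n_transcripts) - 0.5))
  lfc[lfc == 0 & mode != "conserved"] <- de_log2fc
  f_true <- ifelse(mode == "cis", 2^lfc / (1 + 2^lfc), 0.5)
  count_p1 <- rpois(n_transcripts, parent_depth * 2^(lfc / 2))
  count_p2 <- rpois(n_transcripts, parent_depth * 2^(-lfc / 2))
  n <- rpois(n_transcripts, hybrid_depth)
  n_p1 <- rbinom(n_transcripts, n, f_true)
  out <- data.table::data.table(
    transcript_id = sprintf("tx%04d", seq_len(n_transcripts)),
    true_mode = mode, lfc = lfc, f_true = f_true,
    count_p1 = count_p1, count_p2 = count_p2,
    n_p1 = n_p1, n_p2 = n - n_p1)
  data.table::setattr(out, "library_size", library_size)
  data.table::setattr(out, "exon_length", exon_length)
  out[]
}
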