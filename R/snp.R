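#' Consensus base of a parental pileup column
#'
#' A SNP between two inbred parental lines requires each parent's reads to
#' agree on one base. With `max_minor_fraction = 0` (the default) agreement
#' means strict unanimity among quality-passing reads; a small positive value
#' tolerates a minor fraction of discordant reads, accommodating sequencing
#' error in real data.
#'
#' @param counts Named integer vector (or single-row matrix) of A/C/G/T
#'   counts from quality-passing reads.
#' @param max_minor_fraction Maximum tolerated fraction of reads not carrying
#'   the consensus base (default 0 = unanimity).
#' @return The consensus base, or `NA_character_` if no single base carries
#'   at least `1 - max_minor_fraction` of the reads (or depth is zero).
#' @examples
#' consensus_base(c(A = 0, C = 15, G = 0, T = 0))               # "C"
#' consensus_base(c(A = 0, C = 14, G = 0, T = 1))               # NA
#' consensus_base(c(A = 0, C = 14, G = 0, T = 1), 0.1)          # "C"
#' @export
consensus_base <- function(counts, max_minor_fraction = 0) {
  m <- matrix(as.numeric(counts[NUCS]), nrow = 1L,
              dimnames = list(NULL, NUCS))
  consensus_base_matrix(m, max_minor_fraction)$base
}

# vectorized consensus over a sites x ACGT count matrix;
# returns list(base, count, depth) with NA base where no consensus
consensus_base_matrix <- function(m, max_minor_fraction = 0) {
  depth <- rowSums(m)
  top <- max.col(m, ties.method = "first")
  topcount <- m[cbind(seq_len(nrow(m)), top)]
  need <- (1 - max_minor_fraction) * depth
  n_qual <- rowSums(m >= pmax(need, 1e-9))
  ok <- depth > 0 & topcount >= need & n_qual == 1L
  list(base = ifelse(ok, NUCS[top], NA_character_),
       count = topcount, depth = depth)
}

#' Phred-scaled site quality for a candidate inter-parental SNP
#'
#' Scores how strongly a parental pileup column excludes a heterozygous
#' (50/50) site: `-10*log10 P(X <= depth - consensus_count)` for
#' `X ~ Binomial(depth, 0.5)`. The score is monotone non-decreasing in depth
#' for unanimous columns (about 3 phred per read) and is lowered by
#' discordant reads. For a SNP the score is the minimum over the two parents.
#'
#' @param consensus_p1,depth_p1 Consensus-base count and quality-passing
#'   depth of the parent-1 column.
#' @param consensus_p2,depth_p2 Same for parent 2. Omit to score one column.
#' @return Phred-scaled quality (vectorized).
#' @examples
#' site_quality(10, 10)            # 30.1: unanimous at the minimum depth
#' site_quality(15, 15, 12, 12)    # min over the two parents
#' @export
site_quality <- function(consensus_p1, depth_p1,
                         consensus_p2 = NULL, depth_p2 = NULL) {
  q1 <- -10 * pbinom(depth_p1 - consensus_p1, depth_p1, 0.5, log.p = TRUE) /
    log(10)
  if (is.null(consensus_p2)) return(q1)
  pmin(q1, site_quality(consensus_p2, depth_p2))
}

# per-stage candidate table from two parental pileups
stage_candidates <- function(p1, p2, max_minor_fraction) {
  m <- merge(p1, p2, by = c("transcript_id", "chrom", "pos"),
             suffixes = c("_1", "_2"))
  if (!nrow(m))
    return(data.table::data.table(transcript_id = character(),
                                  chrom = character(), pos = integer(),
                                  a1 = character(), a2 = character(),
                                  d1 = numeric(), d2 = numeric(),
                                  qual = numeric()))
  c1 <- consensus_base_matrix(as.matrix(m[, paste0(NUCS, "_1"), with = FALSE]),
                              max_minor_fraction)
  c2 <- consensus_base_matrix(as.matrix(m[, paste0(NUCS, "_2"), with = FALSE]),
                              max_minor_fraction)
  out <- m[, .(transcript_id, chrom, pos)]
  out[, `:=`(a1 = c1$base, a2 = c2$base,
             d1 = c1$count, d2 = c2$count,
             qual = site_quality(c1$count, c1$depth, c2$count, c2$depth))]
  out[!is.na(a1) & !is.na(a2) & a1 != a2]
}

#' Call inter-parental SNPs from stage-resolved parental pileups
#'
#' Applies the SNP discovery criteria: (1) each parent's quality-passing
#' reads produce a consensus base and the two consensus bases differ;
#' (2) at least `min_depth` consensus-supporting reads in each parent at each
#' stage; (3) the site is detected at both developmental stages with an
#' identical allele pair, and its phred-scaled [site_quality()] (minimum over
#' parents and stages) is at least `min_qual`. Sites whose allele pair
#' differs between stages are dropped (and counted in the `dropped_discordant`
#' attribute); positions covered in only one parent or one stage are never
#' called.
#'
#' @param pileups_p1,pileups_p2 Named lists of parental pileup tables, one
#'   per stage (names `tillering`, `heading`); each element either a
#'   `sample_pileup` from [build_pileups()] or its `pileup` data.table.
#' @param min_depth Minimum consensus-supporting reads per parent per stage
#'   (default 10).
#' @param min_qual Minimum site quality (default 20).
#' @param max_minor_fraction Passed to [consensus_base()] (default 0).
#' @return data.table of class `snp_calls`: `transcript_id`, `chrom`, `pos`
#'   (0-based), `allele_p1`, `allele_p2`, `depth_p1`, `depth_p2` (summed over
#'   stages), `qual`, `stages` (`"both"`).
#' @export
call_snps <- function(pileups_p1, pileups_p2, min_depth = 10, min_qual = 20,
                      max_minor_fraction = 0) {
  get_pile <- function(x) if (inherits(x, "sample_pileup")) x$pileup else x
  stages <- ASE_STAGES
  stopifnot(all(stages %in% names(pileups_p1)),
            all(stages %in% names(pileups_p2)))
  cand <- lapply(stages, function(s) {
    cc <- stage_candidates(get_pile(pileups_p1[[s]]), get_pile(pileups_p2[[s]]),
                           max_minor_fraction)
    cc[d1 >= min_depth & d2 >= min_depth]
  })
  m <- merge(cand[[1L]], cand[[2L]], by = c("transcript_id", "chrom", "pos"),
             suffixes = c("_t", "_h"))
  discordant <- m[a1_t != a1_h | a2_t != a2_h]
  if (nrow(discordant))
    message(nrow(discordant),
            " site(s) with stage-discordant alleles dropped")
  m <- m[a1_t == a1_h & a2_t == a2_h]
  snps <- m[, .(transcript_id, chrom, pos,
                allele_p1 = a1_t, allele_p2 = a2_t,
                depth_p1 = d1_t + d1_h, depth_p2 = d2_t + d2_h,
                qual = pmin(qual_t, qual_h),
                stages = "both")]
  snps <- snps[qual >= min_qual]
  data.table::setkey(snps, transcript_id, chrom, pos)
  data.table::setattr(snps, "dropped_discordant", nrow(discordant))
  data.table::setattr(snps, "class", c("snp_calls", class(snps)))
  snps[]
}

#' Substitution classes collapsed by strand complement
#'
#' The twelve directed base substitutions collapse to six classes when a
#' substitution and its reverse complement on the opposite strand are
#' identified (e.g. C>T with G>A). Class labels are oriented parent1 to
#' parent2 with an A or C first base.
#' @export
SPECTRUM_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")

#' Classify directed substitutions into complement-collapsed classes
#'
#' @param from,to Character vectors of parent-1 and parent-2 alleles.
#' @return Factor with levels [SPECTRUM_CLASSES].
#' @export
substitution_class <- function(from, to) {
  stopifnot(length(from) == length(to))
  lab <- paste0(from, ">", to)
  flip <- !from %in% c("A", "C")
  lab[flip] <- paste0(COMPLEMENT[from[flip]], ">", COMPLEMENT[to[flip]])
  factor(lab, levels = SPECTRUM_CLASSES)
}

#' Substitution spectrum of a SNP set
#'
#' Tallies SNPs into the six strand-complement-collapsed substitution
#' classes and reports `ct_ga_fraction`, the share of C<->T / G<->A
#' substitutions (classes C>T and A>G, i.e. all four directed transition
#' types). Under a uniform spectrum this share is 1/3; methylated-cytosine
#' deamination inflates it well above that in plant inter-varietal SNPs.
#'
#' @param snps A `snp_calls` table (or any data.frame with `allele_p1`,
#'   `allele_p2`).
#' @return Object of class `spectrum_summary`: list with `class_counts`
#'   (named integer over [SPECTRUM_CLASSES]), `ct_ga_fraction` and `n`.
#'   For an empty set `ct_ga_fraction` is 0 by convention.
#' @export
substitution_spectrum <- function(snps) {
  cls <- substitution_class(as.character(snps$allele_p1),
                            as.character(snps$allele_p2))
  counts <- table(cls)
  n <- sum(counts)
  ct_ga <- if (n == 0L) 0 else
    unname((counts[["C>T"]] + counts[["A>G"]]) / n)
  structure(list(class_counts = stats::setNames(as.integer(counts),
                                                names(counts)),
                 ct_ga_fraction = ct_ga, n = as.integer(n)),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary>", x$n, "SNPs\n")
  if (x$n) {
    tab <- data.frame(class = names(x$class_counts), n = x$class_counts,
                      fraction = round(x$class_counts / x$n, 4))
    print(tab, row.names = FALSE)
  }
  cat(sprintf("C<->T / G<->A share: %.3f\n", x$ct_ga_fraction))
  invisible(x)
}

#' Write a spectrum summary as TSV
#' @param x A `spectrum_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(x, path) {
  df <- data.frame(class = names(x$class_counts), count = x$class_counts,
                   fraction = if (x$n) x$class_counts / x$n else 0)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
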