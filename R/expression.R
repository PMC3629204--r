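#' Reads per kilobase of exon per million mapped reads
#'
#' `rpkm = read_count / (summed_exon_length/1000) / (total_mapped/1e6)`:
#' linear in the read count, inverse-linear in library size.
#'
#' @param read_count Mapped reads assigned to the transcript (vectorized).
#' @param summed_exon_length Summed exon length in bases (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return RPKM values.
#' @examples
#' compute_rpkm(1000, 1000, 1e6)  # 1000
#' compute_rpkm(500, 2000, 1e7)   # 25
#' @export
compute_rpkm <- function(read_count, summed_exon_length, total_mapped) {
  if (any(summed_exon_length <= 0)) stop("summed_exon_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  read_count / (summed_exon_length / 1000) / (total_mapped / 1e6)
}

#' Fold coverage of a transcript
#'
#' Mapped read count multiplied by the read length (100 bp) and divided by
#' the transcript's summed exon length.
#'
#' @param read_count Mapped reads assigned to the transcript.
#' @param summed_exon_length Summed exon length in bases (> 0).
#' @param read_length Read length in bases (default 100).
#' @return Fold coverage (dimensionless).
#' @examples
#' compute_coverage(30, 1500)  # 2
#' @export
compute_coverage <- function(read_count, summed_exon_length,
                             read_length = 100) {
  if (any(summed_exon_length <= 0)) stop("summed_exon_length must be > 0")
  read_count * read_length / summed_exon_length
}

#' Parental differential expression from pooled counts
#'
#' Tests each transcript for total-expression differences between the two
#' parental lines with a two-sided Fisher exact test on the 2x2 table
#' `(count_p1, total_p1 - count_p1; count_p2, total_p2 - count_p2)` of
#' pooled counts, adjusts p-values by Benjamini-Hochberg, and computes the
#' log2 fold change on pseudocounted RPKM. A transcript is significantly
#' differentially expressed when `fdr <= fdr_threshold` and
#' `|log2_fc| >= lfc_threshold`.
#'
#' @param transcript_id Character vector of transcript identifiers.
#' @param count_p1,count_p2 Pooled read counts per transcript in each parent.
#' @param total_p1,total_p2 Library sizes (scalars).
#' @param exon_length Summed exon lengths per transcript.
#' @param fdr_threshold,lfc_threshold Significance gates (defaults 0.05, 1).
#' @param pseudocount Added to both RPKM values before the ratio
#'   (default 0.5).
#' @return data.table of class `de_calls`: `transcript_id`, `rpkm_p1`,
#'   `rpkm_p2`, `parental_ratio` (pseudocounted RPKM ratio parent1/parent2),
#'   `log2_fc`, `p_value`, `fdr`, `significant`.
#' @export
diff_expression <- function(transcript_id, count_p1, count_p2,
                            total_p1, total_p2, exon_length,
                            fdr_threshold = 0.05, lfc_threshold = 1,
                            pseudocount = 0.5) {
  stopifnot(total_p1 > 0, total_p2 > 0)
  pv <- vapply(seq_along(count_p1), function(i)
    fisher.test(matrix(c(count_p1[i], total_p1 - count_p1[i],
                         count_p2[i], total_p2 - count_p2[i]),
                       nrow = 2L))$p.value, numeric(1L))
  fdr <- p.adjust(pv, method = "BH")
  r1 <- compute_rpkm(count_p1, exon_length, total_p1)
  r2 <- compute_rpkm(count_p2, exon_length, total_p2)
  ratio <- (r1 + pseudocount) / (r2 + pseudocount)
  lfc <- log2(ratio)
  out <- data.table::data.table(
    transcript_id = transcript_id, rpkm_p1 = r1, rpkm_p2 = r2,
    parental_ratio = ratio, log2_fc = lfc, p_value = pv, fdr = fdr,
    significant = fdr <= fdr_threshold & abs(lfc) >= lfc_threshold)
  data.table::setattr(out, "class", c("de_calls", class(out)))
  out[]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin, explicit wrapper over the standard step-up adjustment so the FDR
#' gate used throughout the package is a named, documented operation.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (monotone in the sorted order, in (0, 1]).
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Classify cis/trans regulatory divergence of one transcript
#'
#' Confronts the parental expression ratio (parent1/parent2 of total
#' expression, measured in the parents) with the hybrid allelic ratio at one
#' stage. With a cis-regulatory difference both alleles keep their parental
#' activity in the hybrid, so the allelic ratio mirrors the parental ratio;
#' with a pure trans difference both alleles share the hybrid's cellular
#' environment and allelic expression is balanced. Modes:
#' \describe{
#'   \item{conserved}{no parental difference, no allelic bias.}
#'   \item{cis}{parental difference and allelic bias, with the hybrid
#'     parent-1 count statistically compatible (exact binomial test,
#'     `p >= compat_alpha`) with the fraction implied by the parental ratio
#'     `r/(1+r)`.}
#'   \item{cis_plus_trans}{parental difference and allelic bias, but the
#'     allelic ratio incompatible with the parental ratio.}
#'   \item{trans}{parental difference with balanced allelic expression.}
#'   \item{ambiguous}{allelic bias without a parental difference.}
#' }
#'
#' @param de_significant Logical: parental DE call (vectorized).
#' @param bias_significant Logical: transcript-level allelic bias call.
#' @param n_p1,n_p2 Pooled hybrid allele counts for the transcript-stage.
#' @param parental_ratio Parental expression ratio parent1/parent2.
#' @param compat_alpha Compatibility threshold for the cis test
#'   (default 0.05).
#' @return Character vector of modes.
#' @export
regulation_mode <- function(de_significant, bias_significant, n_p1, n_p2,
                            parental_ratio, compat_alpha = 0.05) {
  n <- length(de_significant)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (is.na(de_significant[i]) || is.na(bias_significant[i]) ||
                  is.na(parental_ratio[i])) {
      NA_character_
    } else if (!de_significant[i] && !bias_significant[i]) {
      "conserved"
    } else if (de_significant[i] && !bias_significant[i]) {
      "trans"
    } else if (!de_significant[i]) {
      "ambiguous"
    } else {
      expected <- parental_ratio[i] / (1 + parental_ratio[i])
      compat <- binom.test(n_p1[i], n_p1[i] + n_p2[i],
                           p = expected)$p.value
      if (compat >= compat_alpha) "cis" else "cis_plus_trans"
    }
  }
  out
}

#' Classify regulation for all transcripts at one stage
#'
#' Merges parental DE calls with hybrid transcript-level bias calls and
#' applies [regulation_mode()]. Transcripts lacking either input receive no
#' call. The hybrid allelic ratio reported is
#' `p1_fraction / (1 - p1_fraction)` from read-weighted pooled counts.
#'
#' @param de A `de_calls` table from [diff_expression()].
#' @param bias Bias calls from [aggregate_transcripts()] carrying pooled
#'   counts; rows for one stage. Hybrid pooled counts are reconstructed from
#'   `supporting_reads` and `p1_fraction`.
#' @param compat_alpha Passed to [regulation_mode()].
#' @return data.table of regulatory calls: `transcript_id`, `stage`,
#'   `parental_ratio`, `allelic_ratio`, `mode`.
#' @export
classify_regulation <- function(de, bias, compat_alpha = 0.05) {
  b <- data.table::as.data.table(bias)
  b <- b[direction != "contradictory"]  # excluded from regulatory analysis
  d <- data.table::as.data.table(de)
  m <- merge(b, d[, .(transcript_id, parental_ratio, de_significant = significant)],
             by = "transcript_id")
  if (!nrow(m))
    return(data.table::data.table(transcript_id = character(),
                                  stage = character(),
                                  parental_ratio = numeric(),
                                  allelic_ratio = numeric(),
                                  mode = character()))
  m[, n_p1 := round(supporting_reads * p1_fraction)]
  m[, n_p2 := supporting_reads - n_p1]
  m[, bias_significant := direction %in% c("p1_biased", "p2_biased")]
  m[, mode := regulation_mode(de_significant, bias_significant, n_p1, n_p2,
                              parental_ratio, compat_alpha)]
  m[, .(transcript_id, stage, parental_ratio,
        allelic_ratio = p1_fraction / (1 - p1_fraction), mode)]
}
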