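#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests whether hybrid reads deviate from the 1:1 ratio expected when both
#' parental alleles are expressed equally. The two-sided p-value uses the
#' minimum-likelihood construction: the sum of `P(k)` over all outcomes `k`
#' whose null probability does not exceed that of the observed count. Under
#' the symmetric null `p = 0.5` this coincides with doubling the smaller
#' tail, and the test is symmetric in its arguments.
#'
#' @param n_p1,n_p2 Integer vectors of hybrid read counts carrying the
#'   parent-1 and parent-2 allele (recycled to a common length).
#' @return Numeric vector of exact two-sided p-values in (0, 1]; `NA` where
#'   `n_p1 + n_p2 == 0`.
#' @examples
#' binomial_bias_test(10, 10)       # 1
#' binomial_bias_test(20, 0)        # 2 * 0.5^20
#' binomial_bias_test(c(16, 17), c(4, 3))  # straddle the P < 0.01 gate
#' @export
binomial_bias_test <- function(n_p1, n_p2) {
  k <- pmin(n_p1, n_p2)
  n <- n_p1 + n_p2
  out <- rep(NA_real_, length(n))
  ok <- !is.na(n) & n > 0L
  # group by n so the pmf is computed once per total
  for (nn in unique(n[ok])) {
    i <- ok & n == nn
    pmf <- dbinom(0:nn, nn, 0.5)
    obs <- pmf[k[i] + 1L]
    out[i] <- vapply(obs, function(p0)
      sum(pmf[pmf <= p0 * (1 + 1e-7)]), numeric(1L))
  }
  pmin(out, 1)
}

#' Exact power of the allelic-bias test
#'
#' Enumerates the rejection region of [binomial_bias_test()] at total depth
#' `n` and significance gate `p < alpha`, and sums the binomial probability
#' of that region under a true parent-1 fraction `p1`.
#'
#' @param n Total allele-informative depth.
#' @param p1 True parent-1 allele fraction.
#' @param alpha Significance gate (strict `<`; default 0.01).
#' @return Exact rejection probability.
#' @export
binomial_test_power <- function(n, p1, alpha = 0.01) {
  pv <- binomial_bias_test(0:n, n:0)
  sum(dbinom(which(pv < alpha) - 1L, n, p1))
}

#' Count parental alleles in hybrid reads at called SNPs
#'
#' For each SNP, looks up the hybrid pileup column and splits its
#' quality-passing reads into those supporting the parent-1 allele, the
#' parent-2 allele, or neither (`n_other`: sequencing errors or third
#' alleles, excluded from testing). Transcripts whose summed SNP-supporting
#' reads (`n_p1 + n_p2` over all their SNPs) fall below `min_support` at this
#' stage are discarded entirely, to preserve the power of downstream
#' transcript-level calls. SNP positions uncovered in the hybrid yield
#' zero-count records that are excluded from testing.
#'
#' @param hybrid_pileup A `sample_pileup` (or its `pileup` data.table) for
#'   the hybrid at one stage.
#' @param snps A `snp_calls` table from [call_snps()].
#' @param stage Stage label stored in the output (`"tillering"`/`"heading"`).
#' @param min_support Minimum summed SNP-supporting hybrid reads per
#'   transcript (default 20).
#' @param test Logical: also compute binomial p-values (default TRUE).
#' @return data.table of ASE records: SNP fields plus `stage`, `n_p1`,
#'   `n_p2`, `n_other`, `p1_fraction`, `p_value`.
#' @export
count_hybrid_alleles <- function(hybrid_pileup, snps, stage,
                                 min_support = 20, test = TRUE) {
  pile <- if (inherits(hybrid_pileup, "sample_pileup")) hybrid_pileup$pileup
          else hybrid_pileup
  rec <- merge(data.table::as.data.table(snps),
               pile[, c("transcript_id", "chrom", "pos", NUCS), with = FALSE],
               by = c("transcript_id", "chrom", "pos"), all.x = TRUE)
  for (b in NUCS) data.table::set(rec, which(is.na(rec[[b]])), b, 0L)
  bm <- as.matrix(rec[, NUCS, with = FALSE])
  ii <- seq_len(nrow(rec))
  rec[, n_p1 := bm[cbind(ii, match(allele_p1, NUCS))]]
  rec[, n_p2 := bm[cbind(ii, match(allele_p2, NUCS))]]
  rec[, n_other := rowSums(bm) - n_p1 - n_p2]
  rec[, (NUCS) := NULL]
  rec[, stage := stage]
  rec[, support := sum(n_p1 + n_p2), by = transcript_id]
  rec <- rec[support >= min_support][, support := NULL]
  rec[, p1_fraction := data.table::fifelse(n_p1 + n_p2 > 0,
                                           n_p1 / (n_p1 + n_p2), NA_real_)]
  if (test) rec[, p_value := binomial_bias_test(n_p1, n_p2)]
  rec[]
}

#' Aggregate SNP-level allelic bias to transcript level
#'
#' Classifies each transcript at one stage from its SNP-level tests: SNPs
#' with `p_value < alpha` are significant; a transcript is `p1_biased` if it
#' has significant SNPs and all of them favour the parent-1 allele
#' (`p1_fraction > 0.5`), `p2_biased` symmetrically, `contradictory` if
#' significant SNPs disagree in direction (such transcripts are excluded
#' from stage-pattern analysis), and `balanced` if no SNP is significant.
#' The transcript's pooled parent-1 fraction is read-weighted:
#' `sum(n_p1) / sum(n_p1 + n_p2)` over its SNPs.
#'
#' @param records ASE records from [count_hybrid_alleles()] (one stage, or
#'   several stages: aggregation is by transcript and stage).
#' @param alpha SNP-level significance gate, strict `<` (default 0.01).
#' @return data.table of bias calls: `transcript_id`, `stage`, `n_snps`,
#'   `n_significant`, `direction`, `supporting_reads`, `p1_fraction`
#'   (pooled), `min_p`.
#' @export
aggregate_transcripts <- function(records, alpha = 0.01) {
  rec <- data.table::as.data.table(records)[n_p1 + n_p2 > 0]
  calls <- rec[, {
    sig <- p_value < alpha
    dir_sig <- sign(p1_fraction[sig] - 0.5)
    direction <- if (!any(sig)) "balanced"
      else if (all(dir_sig > 0)) "p1_biased"
      else if (all(dir_sig < 0)) "p2_biased"
      else "contradictory"
    .(n_snps = .N, n_significant = sum(sig), direction = direction,
      supporting_reads = sum(n_p1 + n_p2),
      p1_fraction = sum(n_p1) / sum(n_p1 + n_p2),
      min_p = min(p_value))
  }, by = .(transcript_id, stage)]
  data.table::setkey(calls, transcript_id, stage)
  calls[]
}

#' Classify per-transcript allelic bias patterns across stages
#'
#' Combines a transcript's bias calls at the two stages into a stage
#' pattern (`both_stages`, `tillering_only`, `heading_only`, `none`) and a
#' strong-bias class. A transcript is strongly biased when its pooled
#' parent-1 fraction is strictly below `strong_lo` or strictly above
#' `strong_hi` at one or both stages; it is then `p1_predominant` or
#' `p2_predominant` when both stage fractions fall on the same side of 0.5,
#' and `switching` when the predominant allele differs between stages.
#' Transcripts with a `contradictory` call at either stage are excluded.
#'
#' @param calls Bias calls from [aggregate_transcripts()] covering both
#'   stages. Only transcripts tested at both stages are classified.
#' @param strong_lo,strong_hi Strong-bias cutoffs on the parent-1 read
#'   fraction (defaults 0.3 and 0.7, strict inequalities).
#' @return data.table: `transcript_id`, `pattern`, `strong_bias`,
#'   `frac_tillering`, `frac_heading`, `dir_tillering`, `dir_heading`.
#' @export
classify_stage_patterns <- function(calls, strong_lo = 0.3, strong_hi = 0.7) {
  cc <- data.table::as.data.table(calls)
  contra <- unique(cc[direction == "contradictory", transcript_id])
  cc <- cc[!transcript_id %in% contra]
  wide <- data.table::dcast(cc, transcript_id ~ stage,
                            value.var = c("direction", "p1_fraction"))
  need <- c("direction_tillering", "direction_heading",
            "p1_fraction_tillering", "p1_fraction_heading")
  if (!all(need %in% names(wide)))
    return(data.table::data.table(transcript_id = character(),
                                  pattern = character(),
                                  strong_bias = character(),
                                  frac_tillering = numeric(),
                                  frac_heading = numeric(),
                                  dir_tillering = character(),
                                  dir_heading = character()))
  wide <- wide[!is.na(direction_tillering) & !is.na(direction_heading)]
  bias_t <- wide$direction_tillering %in% c("p1_biased", "p2_biased")
  bias_h <- wide$direction_heading %in% c("p1_biased", "p2_biased")
  pattern <- data.table::fcase(bias_t & bias_h, "both_stages",
                               bias_t, "tillering_only",
                               bias_h, "heading_only",
                               default = "none")
  ft <- wide$p1_fraction_tillering; fh <- wide$p1_fraction_heading
  strong <- ft < strong_lo | ft > strong_hi | fh < strong_lo | fh > strong_hi
  strong_bias <- data.table::fcase(
    !strong, "none",
    (ft > 0.5) != (fh > 0.5), "switching",
    ft > 0.5, "p1_predominant",
    default = "p2_predominant")
  data.table::data.table(transcript_id = wide$transcript_id,
                         pattern = pattern, strong_bias = strong_bias,
                         frac_tillering = ft, frac_heading = fh,
                         dir_tillering = wide$direction_tillering,
                         dir_heading = wide$direction_heading)
}

#' Census of allelic-bias calls
#'
#' Summarises a full ASE run the way such studies report it: per stage, the
#' number of transcripts tested, biased, and biased toward each parent; and
#' across stages, how many transcripts are biased at at least one stage, at
#' both, or at exactly one, plus the strong-bias class counts. The derived
#' percentages come from [census_percentages()].
#'
#' @param patterns Output of [classify_stage_patterns()].
#' @param calls Output of [aggregate_transcripts()].
#' @return Object of class `ase_census`: list with `counts` (see
#'   [census_percentages()]) and `percentages`.
#' @export
bias_census <- function(patterns, calls) {
  cc <- data.table::as.data.table(calls)
  per_stage <- cc[, .(
    tested = .N,
    biased = sum(direction %in% c("p1_biased", "p2_biased")),
    p1_biased = sum(direction == "p1_biased"),
    p2_biased = sum(direction == "p2_biased"),
    contradictory = sum(direction == "contradictory")), by = stage]
  pt <- data.table::as.data.table(patterns)
  biased_both <- sum(pt$pattern == "both_stages")
  biased_one <- sum(pt$pattern %in% c("tillering_only", "heading_only"))
  counts <- list(
    tested_total = length(unique(cc$transcript_id)),
    per_stage = per_stage[],
    biased_any = biased_both + biased_one,
    biased_both = biased_both,
    biased_one = biased_one,
    both_p1 = sum(pt$pattern == "both_stages" &
                    pt$dir_tillering == "p1_biased" &
                    pt$dir_heading == "p1_biased"),
    both_p2 = sum(pt$pattern == "both_stages" &
                    pt$dir_tillering == "p2_biased" &
                    pt$dir_heading == "p2_biased"),
    strong = c(p1 = sum(pt$strong_bias == "p1_predominant"),
               p2 = sum(pt$strong_bias == "p2_predominant"),
               switching = sum(pt$strong_bias == "switching")))
  structure(list(counts = counts, percentages = census_percentages(counts)),
            class = "ase_census")
}

#' Derived percentages of an allelic-bias census
#'
#' The arithmetic layer of the census, usable directly on printed counts
#' from a report: shares of biased transcripts overall and per stage, the
#' parent-1 share among biased transcripts, the balanced share, the
#' one-stage count and the strong-bias total.
#'
#' @param counts List with `tested_total`, `biased_any`, `biased_both`,
#'   `both_p1`, `strong` (named numeric with `p1`, `p2`, `switching`) and
#'   `per_stage` (data.frame with `stage`, `tested`... here `biased` is the
#'   number of transcripts biased at that stage and `p1_biased` those
#'   favouring parent 1).
#' @return Named numeric vector: `pct_biased_any`, per-stage
#'   `pct_p1_<stage>` and `pct_balanced_<stage>`, `pct_both_p1`,
#'   `n_biased_one`, `n_strong`.
#' @examples
#' census_percentages(list(
#'   tested_total = 2793, biased_any = 480, biased_both = 125, both_p1 = 92,
#'   strong = c(p1 = 20, p2 = 14, switching = 4),
#'   per_stage = data.frame(stage = c("tillering", "heading"),
#'                          biased = c(289, 316), p1_biased = c(195, 195))))
#' @export
census_percentages <- function(counts) {
  ps <- as.data.frame(counts$per_stage)
  out <- c(pct_biased_any = 100 * counts$biased_any / counts$tested_total)
  for (i in seq_len(nrow(ps))) {
    s <- ps$stage[i]
    out[paste0("pct_p1_", s)] <- 100 * ps$p1_biased[i] / ps$biased[i]
    out[paste0("pct_balanced_", s)] <-
      100 * (counts$tested_total - ps$biased[i]) / counts$tested_total
  }
  out["pct_both_p1"] <- 100 * counts$both_p1 / counts$biased_both
  out["n_biased_one"] <- counts$biased_any - counts$biased_both
  out["n_strong"] <- sum(counts$strong)
  out
}

#' @export
print.ase_census <- function(x, ...) {
  ct <- x$counts
  cat("<ase_census>\n")
  cat(sprintf("  transcripts tested (both stages): %d\n", ct$tested_total))
  cat(sprintf("  biased at >=1 stage: %d (both: %d, one: %d)\n",
              ct$biased_any, ct$biased_both, ct$biased_one))
  print(as.data.frame(ct$per_stage), row.names = FALSE)
  cat("  strong bias:", paste(names(ct$strong), ct$strong, sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}
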