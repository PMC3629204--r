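#' Pipeline configuration
#'
#' Collects input paths and the analysis thresholds: minimum
#' consensus-supporting depth per parent per stage (`min_depth`), minimum
#' phred site quality (`min_qual`), minimum SNP-supporting hybrid reads per
#' transcript and stage (`min_support`), the SNP-level allelic-bias
#' significance gate (`alpha`, strict `<`), the parental differential
#' expression gates (`fdr`, `log2fc`), and the strong-bias cutoffs
#' (`strong_lo`/`strong_hi`, strict inequalities on the parent-1 read
#' fraction).
#'
#' @param annotation Path to GFF3 or BED12 annotation.
#' @param sam Nested list `sam[[role]][[stage]]` of SAM/BAM paths (roles
#'   `parent1`, `parent2`, `hybrid`; stages `tillering`, `heading`);
#'   replicate files in one vector are pooled.
#' @param out_dir Output directory for report files; `NULL` for none.
#' @param min_depth,min_qual,min_support,alpha,fdr,log2fc,strong_lo,strong_hi
#'   Thresholds, defaulting to 10, 20, 20, 0.01, 0.05, 1, 0.3 and 0.7.
#' @param max_minor_fraction Consensus tolerance for SNP calling
#'   (default 0 = unanimity).
#' @param compat_alpha Cis-compatibility threshold (default 0.05).
#' @param pseudocount RPKM pseudocount for fold changes (default 0.5).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, sam, out_dir = NULL,
                            min_depth = 10, min_qual = 20, min_support = 20,
                            alpha = 0.01, fdr = 0.05, log2fc = 1,
                            strong_lo = 0.3, strong_hi = 0.7,
                            max_minor_fraction = 0, compat_alpha = 0.05,
                            pseudocount = 0.5) {
  stopifnot(min_depth > 0, min_qual > 0, min_support > 0,
            alpha > 0, fdr > 0, log2fc > 0,
            strong_lo < 0.5, strong_hi > 0.5)
  roles <- c("parent1", "parent2", "hybrid")
  stopifnot(all(roles %in% names(sam)))
  for (r in roles) stopifnot(all(ASE_STAGES %in% names(sam[[r]])))
  structure(as.list(environment())[setdiff(ls(), c("roles", "r"))],
            class = "pipeline_config")
}

#' Squared correlation of replicate expression profiles
#'
#' Agreement between two biological replicates as the squared Pearson
#' correlation of their per-transcript expression vectors, by default on the
#' `log10(x + 1)` scale appropriate for RPKM.
#'
#' @param rep1,rep2 Per-transcript expression vectors over the same
#'   transcripts (length >= 3).
#' @param log Transform to `log10(x + 1)` first (default TRUE).
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
replicate_agreement <- function(rep1, rep2, log = TRUE) {
  stopifnot(length(rep1) == length(rep2), length(rep1) >= 3)
  if (log) {
    rep1 <- log10(rep1 + 1); rep2 <- log10(rep2 + 1)
  }
  cor(rep1, rep2)^2
}

# expression table for one library: counts, RPKM, coverage
expression_table <- function(pile, transcripts, role, stage,
                             read_length = 100) {
  tx <- data.table::as.data.table(transcripts$transcripts)
  m <- merge(tx[, .(transcript_id, summed_exon_length)], pile$read_counts,
             by = "transcript_id", all.x = TRUE)
  m[is.na(n_reads), n_reads := 0L]
  total <- sum(pile$total_reads)
  m[, `:=`(role = role, stage = stage, total_mapped = total,
           rpkm = compute_rpkm(n_reads, summed_exon_length, total),
           coverage = compute_coverage(n_reads, summed_exon_length,
                                       read_length))]
  m[]
}

#' Run the complete allele-specific expression pipeline
#'
#' Orchestrates every stage on one dataset: annotation loading, pileup
#' construction per role and stage (replicates pooled), SNP calling with
#' stage concordance, substitution-spectrum summary, hybrid allele counting
#' and binomial bias testing, transcript aggregation, stage-pattern
#' classification and census, expression metrics, parental differential
#' expression, cis/trans regulatory classification, and replicate-agreement
#' R-squared. When `config$out_dir` is set, writes the SNP VCF, per-SNP and
#' per-transcript ASE tables, census, expression, DE, regulation and
#' spectrum tables, the replicate-agreement table and a JSON run manifest
#' (package version, thresholds, input checksums).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `ase_run`: list with `snps`, `spectrum`,
#'   `ase_records`, `bias_calls`, `patterns`, `census`, `expression`, `de`,
#'   `regulation`, `replicate_r2`, `files` (written paths) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_fail <- function(stage_name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage_name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  ts <- stage_fail("annotation", load_annotation(config$annotation))
  piles <- stage_fail("pileup", {
    lapply(config$sam, function(stages)
      lapply(stages, function(paths) build_pileups(paths, ts)))
  })
  snps <- stage_fail("snp_discovery",
    call_snps(piles$parent1, piles$parent2,
              min_depth = config$min_depth, min_qual = config$min_qual,
              max_minor_fraction = config$max_minor_fraction))
  spectrum <- substitution_spectrum(snps)
  records <- stage_fail("ase_counting", data.table::rbindlist(
    lapply(ASE_STAGES, function(s)
      count_hybrid_alleles(piles$hybrid[[s]], snps, s,
                           min_support = config$min_support))))
  calls <- aggregate_transcripts(records, alpha = config$alpha)
  patterns <- classify_stage_patterns(calls, config$strong_lo,
                                      config$strong_hi)
  census <- bias_census(patterns, calls)
  expr <- data.table::rbindlist(lapply(names(piles), function(role)
    data.table::rbindlist(lapply(ASE_STAGES, function(s)
      expression_table(piles[[role]][[s]], ts, role, s)))))
  de <- data.table::rbindlist(lapply(ASE_STAGES, function(s) {
    e1 <- expr[role == "parent1" & stage == s]
    e2 <- expr[role == "parent2" & stage == s]
    m <- merge(e1[, .(transcript_id, summed_exon_length, n1 = n_reads,
                      t1 = total_mapped)],
               e2[, .(transcript_id, n2 = n_reads, t2 = total_mapped)],
               by = "transcript_id")
    d <- diff_expression(m$transcript_id, m$n1, m$n2, m$t1[1L], m$t2[1L],
                         m$summed_exon_length,
                         fdr_threshold = config$fdr,
                         lfc_threshold = config$log2fc,
                         pseudocount = config$pseudocount)
    d[, stage := s]
    d
  }))
  regulation <- data.table::rbindlist(lapply(ASE_STAGES, function(s)
    classify_regulation(de[stage == s], calls[stage == s],
                        compat_alpha = config$compat_alpha)))
  rep_r2 <- data.table::rbindlist(lapply(names(piles), function(role)
    data.table::rbindlist(lapply(ASE_STAGES, function(s) {
      p <- piles[[role]][[s]]
      if (p$n_files < 2L) return(NULL)
      rc <- data.table::dcast(p$read_counts_by_file, transcript_id ~ file,
                              value.var = "n_reads", fill = 0L)
      tx <- merge(rc,
                  data.table::as.data.table(
                    ts$transcripts)[, .(transcript_id, summed_exon_length)],
                  by = "transcript_id")
      files <- setdiff(names(rc), "transcript_id")
      r2 <- vapply(utils::combn(files, 2L, simplify = FALSE), function(pr) {
        tot <- p$total_reads[pr]
        replicate_agreement(
          compute_rpkm(tx[[pr[1L]]], tx$summed_exon_length, tot[1L]),
          compute_rpkm(tx[[pr[2L]]], tx$summed_exon_length, tot[2L]))
      }, numeric(1L))
      data.table::data.table(role = role, stage = s, r_squared = r2)
    }))))
  res <- structure(list(snps = snps, spectrum = spectrum,
                        ase_records = records, bias_calls = calls,
                        patterns = patterns, census = census,
                        expression = expr, de = de, regulation = regulation,
                        replicate_r2 = rep_r2, files = character(),
                        config = config),
                   class = "ase_run")
  if (!is.null(config$out_dir)) res$files <- write_run_outputs(res, config)
  res
}

# serialise every report artifact; returns the named file vector
write_run_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(config$out_dir, name)
  files <- c(snps = f("snps.vcf"), spectrum = f("spectrum.tsv"),
             ase = f("ase_snp.tsv"), bias = f("bias_transcripts.tsv"),
             census = f("census.tsv"), expression = f("expression.tsv"),
             de = f("diff_expression.tsv"), regulation = f("regulation.tsv"),
             replicate_r2 = f("replicate_r2.tsv"),
             manifest = f("manifest.json"))
  write_snp_vcf(res$snps, files[["snps"]])
  write_spectrum_tsv(res$spectrum, files[["spectrum"]])
  data.table::fwrite(res$ase_records, files[["ase"]], sep = "\t")
  data.table::fwrite(res$bias_calls, files[["bias"]], sep = "\t")
  ct <- res$census$counts
  census_flat <- data.table::data.table(
    metric = c("tested_total", "biased_any", "biased_both", "biased_one",
               "both_p1", "both_p2", paste0("strong_", names(ct$strong)),
               names(res$census$percentages)),
    value = c(ct$tested_total, ct$biased_any, ct$biased_both, ct$biased_one,
              ct$both_p1, ct$both_p2, unname(ct$strong),
              unname(res$census$percentages)))
  data.table::fwrite(census_flat, files[["census"]], sep = "\t")
  data.table::fwrite(res$expression, files[["expression"]], sep = "\t")
  data.table::fwrite(res$de, files[["de"]], sep = "\t")
  data.table::fwrite(res$regulation, files[["regulation"]], sep = "\t")
  data.table::fwrite(res$replicate_r2, files[["replicate_r2"]], sep = "\t")
  inputs <- c(annotation = config$annotation,
              unlist(config$sam, use.names = TRUE))
  manifest <- list(
    package = "asepipe",
    version = as.character(utils::packageVersion("asepipe")),
    thresholds = config[c("min_depth", "min_qual", "min_support", "alpha",
                          "fdr", "log2fc", "strong_lo", "strong_hi",
                          "max_minor_fraction", "compat_alpha",
                          "pseudocount")],
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(files[names(files) != "manifest"]))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  files
}

#' @export
print.ase_run <- function(x, ...) {
  cat("<ase_run>\n")
  cat(sprintf("  SNPs called: %d (C<->T/G<->A share %.3f)\n",
              nrow(x$snps), x$spectrum$ct_ga_fraction))
  cat(sprintf("  transcripts with bias calls: %d\n",
              length(unique(x$bias_calls$transcript_id))))
  cat(sprintf("  biased at >=1 stage: %d\n", x$census$counts$biased_any))
  if (nrow(x$replicate_r2))
    cat(sprintf("  replicate R^2: %.3f-%.3f\n", min(x$replicate_r2$r_squared),
                max(x$replicate_r2$r_squared)))
  invisible(x)
}
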