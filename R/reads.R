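#' Quality filter and end-trim for one aligned read
#'
#' Implements the read-level quality policy applied before pileup
#' construction: a read is discarded when more than 30% of its bases have
#' base quality below Q20 (strictly more; a read with exactly 30% low-quality
#' bases is kept), and low-quality (Q<20) bases at the 5' and 3' ends of kept
#' reads are trimmed, i.e. excluded from the pileup entirely. Interior Q<20
#' bases are retained by the read but counted as `other` in pileup columns.
#'
#' @param qual Base qualities of one read: an integer vector of phred scores,
#'   or a single character string in phred+33 encoding.
#' @param max_low_frac Maximum tolerated fraction of bases below `min_q`
#'   (default 0.3); reads strictly above it are discarded.
#' @param min_q Phred threshold below which a base counts as low quality
#'   (default 20).
#' @param missing_quality Policy when qualities are absent (`"*"` in SAM):
#'   `"discard"` (default, with a warning) or `"keep"` (treat all bases as
#'   high quality).
#' @return A list with `keep` (logical), and for kept reads `from`/`to`, the
#'   1-based first and last base positions surviving end-trimming (`NA` for
#'   discarded reads or reads with no Q>=`min_q` base).
#' @examples
#' read_filter(c(rep(30, 69), rep(10, 31)))$keep  # FALSE: 31% low quality
#' read_filter(c(rep(30, 70), rep(10, 30)))$keep  # TRUE: exactly 30%
#' read_filter(c(10, 10, 30, 30, 30, 10))[c("from", "to")]  # 3, 5
#' @export
read_filter <- function(qual, max_low_frac = 0.3, min_q = 20,
                        missing_quality = c("discard", "keep")) {
  missing_quality <- match.arg(missing_quality)
  if (is.character(qual)) {
    if (identical(qual, "*") || !nzchar(qual)) {
      if (missing_quality == "discard") {
        warning("read without base qualities discarded")
        return(list(keep = FALSE, from = NA_integer_, to = NA_integer_))
      }
      qual <- rep.int(41L, 1L)  # single placeholder base treated high-quality
    } else {
      qual <- utf8ToInt(qual) - 33L
    }
  }
  n <- length(qual)
  low <- qual < min_q
  if (sum(low) > max_low_frac * n)
    return(list(keep = FALSE, from = NA_integer_, to = NA_integer_))
  hi <- which(!low)
  if (!length(hi))
    return(list(keep = TRUE, from = NA_integer_, to = NA_integer_))
  list(keep = TRUE, from = hi[1L], to = hi[length(hi)])
}

# Read primary mapped alignments from a SAM (or BAM) file via htslib.
# Returns a list: data.table(qname, chrom, pos1, cigar), character seqs,
# IntegerList quals.
read_alignments <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(res$pos)
  list(meta = data.table::data.table(qname = res$qname[keep],
                                     chrom = as.character(res$rname[keep]),
                                     pos1 = res$pos[keep],
                                     cigar = res$cigar[keep]),
       seq = as.character(res$seq[keep]),
       qual = methods::as(res$qual[keep], "IntegerList"))
}

# Expand alignments to per-base records after read filtering and end
# trimming. Returns data.table(read_id, chrom, pos0, base, q).
expand_alignments <- function(aln, max_low_frac = 0.3, min_q = 20) {
  quals <- aln$qual
  n <- length(quals)
  if (!n) return(data.table::data.table(read_id = integer(), chrom = character(),
                                        pos0 = integer(), base = character(),
                                        q = integer()))
  lens <- S4Vectors::elementNROWS(quals)
  low <- quals < min_q
  n_low <- sum(low)
  keep <- n_low <= max_low_frac * lens
  # trim bounds: first/last high-quality base of each kept read
  hipos <- BiocGenerics::which(!low)
  from <- suppressWarnings(min(hipos))  # Inf where no high-quality base
  to <- suppressWarnings(max(hipos))
  keep <- keep & is.finite(from)
  idx <- which(keep)
  if (!length(idx)) return(expand_alignments(list(qual = quals[0]), max_low_frac, min_q))
  meta <- aln$meta[idx]
  # reference/query coordinates of aligned blocks
  ops <- c("M", "=", "X")
  refr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    meta$cigar, pos = meta$pos1, ops = ops)
  qryr <- GenomicAlignments::cigarRangesAlongQuerySpace(meta$cigar, ops = ops)
  nb <- S4Vectors::elementNROWS(refr)
  uref <- BiocGenerics::unlist(refr, use.names = FALSE)
  uqry <- BiocGenerics::unlist(qryr, use.names = FALSE)
  w <- BiocGenerics::width(uref)
  block_read <- rep(seq_along(idx), nb)
  off <- sequence(w) - 1L
  base_read <- rep(block_read, w)
  refpos1 <- rep(BiocGenerics::start(uref), w) + off
  qrypos <- rep(BiocGenerics::start(uqry), w) + off
  # drop end-trimmed query positions
  ok <- qrypos >= from[idx][base_read] & qrypos <= to[idx][base_read]
  base_read <- base_read[ok]; refpos1 <- refpos1[ok]; qrypos <- qrypos[ok]
  # pull base characters and qualities by flat offsets
  all_chars <- strsplit(aln$seq[idx], "", fixed = TRUE)
  flat_chars <- unlist(all_chars, use.names = FALSE)
  flat_q <- BiocGenerics::unlist(quals[idx], use.names = FALSE)
  offset0 <- cumsum(c(0L, lens[idx][-length(idx)]))
  flat_i <- offset0[base_read] + qrypos
  data.table::data.table(read_id = idx[base_read],
                         chrom = meta$chrom[base_read],
                         pos0 = refpos1 - 1L,
                         base = flat_chars[flat_i],
                         q = flat_q[flat_i])
}

#' Build exon-restricted pileups from SAM alignments
#'
#' Reads one or more SAM/BAM files (replicates of one library are pooled),
#' applies the read-level quality filter and end-trimming of [read_filter()],
#' and tallies per-position base counts restricted to annotated exons.
#' Secondary, supplementary and unmapped alignments are excluded; duplicates
#' are kept. In each pileup column, bases A/C/G/T with quality >= `min_q`
#' are counted toward their base; N bases and interior low-quality bases are
#' counted as `other`. Counts are conserved: at every column the base counts
#' plus `other` equal the number of retained read bases covering that exonic
#' position.
#'
#' @param paths Character vector of SAM/BAM paths (replicates, pooled).
#' @param transcripts A `transcript_set` from [load_annotation()].
#' @param min_q Per-base quality threshold (default 20).
#' @param max_low_frac Read-level low-quality tolerance (default 0.3).
#' @return An object of class `sample_pileup`: a list with
#'   `pileup` (data.table: `transcript_id`, `chrom`, `pos` 0-based,
#'   `A`,`C`,`G`,`T`,`other`), `read_counts` (retained reads overlapping each
#'   transcript's exons, per file and pooled), `total_reads` (retained
#'   primary mapped reads per file) and `n_files`.
#' @export
build_pileups <- function(paths, transcripts, min_q = 20, max_low_frac = 0.3) {
  stopifnot(inherits(transcripts, "transcript_set"))
  exgr <- exon_granges(transcripts)
  known <- unique(transcripts$transcripts$chrom)
  per_file <- lapply(paths, function(p) {
    aln <- read_alignments(p)
    seen <- unique(aln$meta$chrom)
    bad <- setdiff(seen, known)
    if (length(bad))
      stop("alignment sequences absent from annotation: ",
           paste(bad, collapse = ", "), " (file ", p, ")")
    bases <- expand_alignments(aln, max_low_frac = max_low_frac, min_q = min_q)
    n_retained <- length(unique(bases$read_id))
    if (!nrow(bases)) {
      return(list(pile = data.table::data.table(
        transcript_id = character(), chrom = character(), pos = integer(),
        A = integer(), C = integer(), G = integer(), T = integer(),
        other = integer()),
        rc = data.table::data.table(transcript_id = character(),
                                    n_reads = integer()),
        total = n_retained))
    }
    pgr <- GenomicRanges::GRanges(bases$chrom,
                                  IRanges::IRanges(bases$pos0 + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(pgr, exgr)
    qi <- S4Vectors::queryHits(hits)
    tx <- S4Vectors::mcols(exgr)$transcript_id[S4Vectors::subjectHits(hits)]
    eb <- bases[qi][, transcript_id := tx]
    eb[, cat := data.table::fifelse(q >= min_q & base %chin% NUCS, base, "other")]
    pile <- data.table::dcast(
      eb[, .N, by = .(transcript_id, chrom, pos = pos0, cat)],
      transcript_id + chrom + pos ~ cat, value.var = "N", fill = 0L)
    for (b in c(NUCS, "other"))
      if (!b %in% names(pile)) pile[, (b) := 0L]
    rc <- unique(eb[, .(read_id, transcript_id)])[, .(n_reads = .N),
                                                  by = transcript_id]
    list(pile = pile[, c("transcript_id", "chrom", "pos", NUCS, "other"),
                     with = FALSE],
         rc = rc, total = n_retained)
  })
  pooled <- data.table::rbindlist(lapply(per_file, `[[`, "pile"))
  if (nrow(pooled)) {
    pooled <- pooled[, lapply(.SD, sum), by = .(transcript_id, chrom, pos),
                     .SDcols = c(NUCS, "other")]
    data.table::setkey(pooled, transcript_id, chrom, pos)
  }
  rc <- data.table::rbindlist(lapply(seq_along(per_file), function(i)
    per_file[[i]]$rc[, file := basename(paths[i])]))
  rc_pooled <- if (nrow(rc)) rc[, .(n_reads = sum(n_reads)), by = transcript_id]
               else data.table::data.table(transcript_id = character(),
                                           n_reads = integer())
  structure(list(pileup = pooled, read_counts = rc_pooled,
                 read_counts_by_file = rc,
                 total_reads = stats::setNames(
                   vapply(per_file, `[[`, numeric(1L), "total"),
                   basename(paths)),
                 n_files = length(paths)),
            class = "sample_pileup")
}

#' @export
print.sample_pileup <- function(x, ...) {
  cat(sprintf("<sample_pileup> %d exonic columns, %d transcripts, %s reads (%d file(s))\n",
              nrow(x$pileup), nrow(x$read_counts),
              format(sum(x$total_reads), big.mark = ","), x$n_files))
  invisible(x)
}
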