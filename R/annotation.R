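#' Construct a transcript set
#'
#' Internal constructor for the container holding transcript models: exon
#' structure, strand and summed exon length of each annotated transcript.
#' Exons are stored 0-based half-open; overlapping exon records within one
#' transcript are merged before construction.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`
#'   (0-based), `end` (half-open), `strand`.
#' @return An object of class `transcript_set` with elements `transcripts`
#'   (one row per transcript: `transcript_id`, `chrom`, `strand`, `n_exons`,
#'   `summed_exon_length`) and `exons`.
#' @keywords internal
new_transcript_set <- function(exons) {
  ex <- data.table::as.data.table(exons)
  stopifnot(all(c("transcript_id", "chrom", "start", "end", "strand") %in%
                  names(ex)))
  ex <- ex[order(transcript_id, start)]
  if (nrow(ex) && any(ex$end <= ex$start))
    stop("exon with non-positive length")
  tx <- ex[, .(chrom = chrom[1L], strand = strand[1L], n_exons = .N,
               summed_exon_length = sum(end - start)),
           by = transcript_id]
  structure(list(transcripts = tx[], exons = ex[]), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcripts, %d exons, %d sequence(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

# merge overlapping/adjacent exon intervals of one transcript (0-based input)
merge_exon_intervals <- function(start, end) {
  r <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
  list(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
}

#' Load transcript models from GFF3 or BED12 annotation
#'
#' Reads a transcript annotation and returns the exon structure of each
#' transcript as a [new_transcript_set()] object, the coordinate frame for
#' all downstream SNP and expression analysis. For GFF3, features of type
#' `exon` are grouped by their `Parent` attribute; for BED12 each record is
#' one transcript and its blocks are the exons. Overlapping exon records
#' within a transcript are merged; transcripts with zero exon length are
#' rejected with a warning.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` (BED12) file.
#' @param format `"auto"` (from the file extension), `"gff3"` or `"bed"`.
#' @return A `transcript_set`; empty (with a warning) if the file contains no
#'   usable features.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t400\ttx1\t0\t+\t100\t400\t0\t2\t100,100\t0,200", bed)
#' ts <- load_annotation(bed)
#' ts$transcripts$summed_exon_length  # 200
#' @export
load_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  empty <- function(msg) {
    warning("no transcripts loaded from ", path, ": ", msg)
    new_transcript_set(data.frame(transcript_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(lines) & !startsWith(lines, "#")))
    return(empty("empty file"))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (format == "bed") {
    if (is.null(S4Vectors::mcols(gr)$blocks))
      stop("BED file lacks block (exon) columns; BED12 required: ", path)
    blocks <- S4Vectors::mcols(gr)$blocks
    nb <- S4Vectors::elementNROWS(blocks)
    ub <- BiocGenerics::unlist(blocks, use.names = FALSE)
    chromstart0 <- rep(BiocGenerics::start(gr) - 1L, nb)
    ex <- data.frame(
      transcript_id = rep(as.character(S4Vectors::mcols(gr)$name), nb),
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), nb),
      start = chromstart0 + BiocGenerics::start(ub) - 1L,
      end = chromstart0 + BiocGenerics::end(ub),
      strand = rep(as.character(BiocGenerics::strand(gr)), nb))
  } else {
    gr <- gr[S4Vectors::mcols(gr)$type %in% "exon"]
    if (!length(gr)) return(empty("no exon features"))
    parent <- S4Vectors::mcols(gr)$Parent
    pid <- if (is.null(parent)) S4Vectors::mcols(gr)$transcript_id
           else vapply(as.list(parent), function(p)
             if (length(p)) as.character(p[[1L]]) else NA_character_,
             character(1L))
    if (all(is.na(pid))) stop("GFF3 exons carry no Parent/transcript_id: ", path)
    ex <- data.frame(
      transcript_id = sub("^transcript:", "", pid),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)))
  }
  ex <- data.table::as.data.table(ex)[!is.na(transcript_id)]
  if (!nrow(ex)) return(empty("no exon records"))
  ex <- ex[, merge_exon_intervals(start, end),
           by = .(transcript_id, chrom, strand)]
  bad <- ex[, .(len = sum(end - start)), by = transcript_id][len <= 0]
  if (nrow(bad)) {
    warning("rejecting ", nrow(bad), " transcript(s) with zero exon length: ",
            paste(utils::head(bad$transcript_id, 5L), collapse = ", "))
    ex <- ex[!transcript_id %in% bad$transcript_id]
  }
  new_transcript_set(ex[, .(transcript_id, chrom, start, end, strand)])
}

# GRanges of all exons (1-based), transcript_id in mcols; for overlap joins
exon_granges <- function(ts) {
  ex <- ts$exons
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  gr
}
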