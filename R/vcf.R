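#' Write called SNPs as VCF 4.2
#'
#' Serialises a `snp_calls` table. Internal 0-based positions become 1-based
#' `POS`; `REF` is the parent-1 allele and `ALT` the parent-2 allele; `QUAL`
#' is the phred site quality; `INFO` carries the per-parent supporting
#' depths (`DP1`, `DP2`), the host transcript (`TX`) and the stage flag
#' (`ST=both` for sites confirmed at both stages). An empty SNP set yields a
#' header-only file.
#'
#' @param snps `snp_calls` table from [call_snps()].
#' @param path Output path.
#' @param contigs Optional named integer vector of sequence lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=asepipe",
           "##INFO=<ID=DP1,Number=1,Type=Integer,Description=\"Supporting reads in parent 1\">",
           "##INFO=<ID=DP2,Number=1,Type=Integer,Description=\"Supporting reads in parent 2\">",
           "##INFO=<ID=TX,Number=1,Type=String,Description=\"Transcript\">",
           "##INFO=<ID=ST,Number=1,Type=String,Description=\"Stages at which the SNP was detected\">")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  body <- character()
  if (nrow(snps)) {
    s <- data.table::as.data.table(snps)
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\tDP1=%d;DP2=%d;TX=%s;ST=%s",
                    s$chrom, s$pos + 1L, ".", s$allele_p1, s$allele_p2,
                    formatC(s$qual, format = "f", digits = 2),
                    as.integer(s$depth_p1), as.integer(s$depth_p2),
                    s$transcript_id, s$stages)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_snp_vcf()]
#'
#' Round-trips the SNP table: positions return to the internal 0-based
#' frame and the INFO fields are unpacked.
#'
#' @param path VCF path.
#' @return `snp_calls`-shaped data.table.
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  empty <- data.table::data.table(transcript_id = character(),
                                  chrom = character(), pos = integer(),
                                  allele_p1 = character(),
                                  allele_p2 = character(),
                                  depth_p1 = integer(), depth_p2 = integer(),
                                  qual = numeric(), stages = character())
  if (!length(lines)) return(empty)
  f <- data.table::fread(text = lines, sep = "\t", header = FALSE)
  info_get <- function(info, key)
    sub(paste0(".*", key, "=([^;]+).*"), "\\1", info)
  out <- data.table::data.table(
    transcript_id = info_get(f$V8, "TX"),
    chrom = as.character(f$V1), pos = f$V2 - 1L,
    allele_p1 = f$V4, allele_p2 = f$V5,
    depth_p1 = as.integer(info_get(f$V8, "DP1")),
    depth_p2 = as.integer(info_get(f$V8, "DP2")),
    qual = as.numeric(f$V6), stages = info_get(f$V8, "ST"))
  data.table::setkey(out, transcript_id, chrom, pos)
  out[]
}
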