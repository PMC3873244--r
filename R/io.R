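#' Read a region sequence from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' sequences with names truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_region_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a sequence to FASTA
#'
#' @param sequence Character string or `DNAString`.
#' @param path Output file.
#' @param name Record name.
#' @export
write_region_fasta <- function(sequence, path, name = "region") {
  set <- Biostrings::DNAStringSet(as.character(sequence))
  names(set) <- name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a restriction-fragment map as BED6
#'
#' One record per fragment with `name` = fragment index and `score` =
#' fragment length in bp. BED's 0-based half-open convention is handled by
#' rtracklayer on export.
#'
#' @param fragments `GRanges` from [digest()].
#' @param path Output BED file.
#' @export
write_fragments_bed <- function(fragments, path) {
  gr <- GenomicRanges::granges(fragments)
  S4Vectors::mcols(gr)$name <- as.character(S4Vectors::mcols(fragments)$index)
  S4Vectors::mcols(gr)$score <- BiocGenerics::width(fragments)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' @param path BED file (3-6 columns).
#' @return `GRanges` (1-based closed coordinates; conversion from BED's
#'   0-based half-open convention is handled by rtracklayer).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write genomic intervals to BED
#'
#' @param gr `GRanges`; `name` and `score` metadata columns are written when
#'   present.
#' @param path Output BED file.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read junction reads from a TSV fixture table
#'
#' Expected columns: `sequence`, `quality`, optionally `true_forward`,
#' `true_reverse` and `class` (planted-truth columns written by
#' [simulate_reads()] / [simulate_scenario()]).
#'
#' @param path TSV file with header.
#' @return data.frame of reads.
#' @export
read_reads_tsv <- function(path) {
  reads <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "quality") %in% names(reads))) {
    stop("reads TSV must have 'sequence' and 'quality' columns")
  }
  reads$quality <- as.integer(reads$quality)
  reads
}

#' Write junction reads to a TSV fixture table
#'
#' @param reads data.frame with at least `sequence` and `quality`.
#' @param path Output file.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read junction reads from FASTQ
#'
#' The per-read quality score used by [filter_reads()] is the minimum Phred
#' base quality of the read, a conservative stand-in for a mapping quality
#' when only base qualities are available.
#'
#' @param path FASTQ file.
#' @return data.frame with `sequence` and `quality` columns.
#' @export
read_reads_fastq <- function(path) {
  fq <- Biostrings::readQualityScaledDNAStringSet(path)
  quals <- methods::as(Biostrings::quality(fq), "IntegerList")
  data.frame(
    sequence = as.character(fq),
    quality = as.integer(min(quals)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
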