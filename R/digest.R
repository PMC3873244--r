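#' Restriction site and 5C tail constants
#'
#' `ECORI_SITE` is the EcoRI recognition sequence used throughout as the
#' default restriction site. `CUT_OFFSET` fixes the in-silico cut-placement
#' convention: the fragment boundary is placed at the first base of each
#' recognition-site occurrence, so every internal fragment begins with the
#' intact site. Downstream logic depends only on fragment identity, so any
#' fixed offset would do; this one makes ligation-junction references
#' reconstitute the site at the joint.
#'
#' @name fivec-constants
#' @keywords internal
NULL

ECORI_SITE <- "GAATTC"
CUT_OFFSET <- 0L

EXCLUSION_REASONS <- c("none", "too_large", "too_small")

#' In-silico restriction digestion of a sequence
#'
#' Cuts a nucleotide sequence at every occurrence of a recognition site and
#' returns the resulting ordered, abutting restriction fragments. The cut is
#' placed at the first base of each site occurrence (see [fivec-constants]),
#' so fragments tile the sequence exactly: fragment widths sum to the
#' sequence length and the fragment count equals the number of
#' (non-overlapping) site occurrences plus one. Overlapping occurrences of a
#' user-supplied site are resolved left-to-right greedily; EcoRI's site
#' cannot overlap itself.
#'
#' @param sequence A single nucleotide sequence: a character string, a
#'   [Biostrings::DNAString], or a length-1 [Biostrings::DNAStringSet].
#'   Must be non-empty and contain only A/C/G/T/N (uppercase).
#' @param site Recognition site, A/C/G/T only. Default EcoRI (`"GAATTC"`).
#' @param seq_name Sequence (chromosome) name used for the fragment
#'   coordinates. Taken from the `DNAStringSet` names when available.
#' @return A [GenomicRanges::GRanges] of fragments in genomic order with
#'   metadata columns `index` (ordinal), `eligible` (`NA` until
#'   [filter_fragments()] is applied) and `exclusion_reason`.
#' @examples
#' frags <- digest(paste0(strrep("A", 8), "GAATTC", strrep("T", 10)))
#' GenomicRanges::width(frags)
#' @seealso [filter_fragments()]
#' @export
digest <- function(sequence, site = ECORI_SITE, seq_name = "region") {
  if (methods::is(sequence, "DNAStringSet")) {
    if (length(sequence) != 1L) {
      stop("'sequence' must contain exactly one sequence")
    }
    if (!is.null(names(sequence))) {
      seq_name <- sub("\\s.*$", "", names(sequence)[1L])
    }
    sequence <- sequence[[1L]]
  }
  seq_chr <- as.character(sequence)
  if (length(seq_chr) != 1L || is.na(seq_chr) || nchar(seq_chr) == 0L) {
    stop("'sequence' must be a single non-empty nucleotide string")
  }
  if (grepl("[^ACGTN]", seq_chr)) {
    stop("'sequence' may contain only uppercase A, C, G, T or N")
  }
  if (!is.character(site) || length(site) != 1L || nchar(site) == 0L ||
      grepl("[^ACGT]", site)) {
    stop("'site' must be a non-empty string over A, C, G, T")
  }
  len <- nchar(seq_chr)

  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(seq_chr))
  starts <- BiocGenerics::start(hits)
  # resolve overlapping occurrences left-to-right (impossible for GAATTC,
  # possible for e.g. "AAA")
  if (length(starts) > 1L) {
    keep <- logical(length(starts))
    last_end <- -1L
    for (i in seq_along(starts)) {
      if (starts[i] > last_end) {
        keep[i] <- TRUE
        last_end <- starts[i] + nchar(site) - 1L
      }
    }
    starts <- starts[keep]
  }

  cuts <- starts + CUT_OFFSET
  cuts <- cuts[cuts > 1L & cuts <= len]
  bounds <- c(1L, cuts, len + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = seq_name,
    ranges = IRanges::IRanges(
      start = bounds[-length(bounds)],
      end = bounds[-1L] - 1L
    ),
    strand = "*"
  )
  S4Vectors::mcols(gr)$index <- seq_along(gr)
  S4Vectors::mcols(gr)$eligible <- NA
  S4Vectors::mcols(gr)$exclusion_reason <- NA_character_
  gr
}

#' Flag restriction fragments eligible for 5C primer design
#'
#' Marks each fragment as eligible for primer placement unless it is larger
#' than `max_len` or smaller than `min_len`. The size cut-offs are read
#' strictly (a fragment of exactly `min_len` or `max_len` is eligible).
#' Coordinates and ordering are never altered.
#'
#' @param fragments `GRanges` from [digest()].
#' @param max_len Maximum fragment length in bp (default 20,000).
#' @param min_len Minimum fragment length in bp (default 100).
#' @return The same `GRanges` with `eligible` and `exclusion_reason`
#'   (`"none"`, `"too_large"` or `"too_small"`) filled in.
#' @export
filter_fragments <- function(fragments, max_len = 20000L, min_len = 100L) {
  stopifnot(methods::is(fragments, "GRanges"))
  if (min_len > max_len) stop("'min_len' must not exceed 'max_len'")
  w <- BiocGenerics::width(fragments)
  reason <- rep("none", length(fragments))
  reason[w > max_len] <- "too_large"
  reason[w < min_len] <- "too_small"
  S4Vectors::mcols(fragments)$eligible <- reason == "none"
  S4Vectors::mcols(fragments)$exclusion_reason <- reason
  fragments
}

#' Test whether two genomic intervals overlap
#'
#' Element-wise overlap test requiring at least `min_bp` shared base pairs.
#' Intervals on different sequences never overlap. `a` and `b` are compared
#' pairwise and must have equal length (or one of them length 1, which is
#' recycled).
#'
#' @param a,b `GRanges` objects.
#' @param min_bp Minimum overlap in bp (>= 1).
#' @return Logical vector.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  if (!is.numeric(min_bp) || length(min_bp) != 1L || min_bp < 1) {
    stop("'min_bp' must be a single value >= 1")
  }
  as.logical(IRanges::poverlaps(a, b, minoverlap = as.integer(min_bp)))
}
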