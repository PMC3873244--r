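#' 5C sequencing-adapter tails
#'
#' Universal tails appended to 5C primer cores: forward primers carry the
#' A-key tail at their 5' end, reverse primers the P1-key tail at their 3'
#' end. Reverse primers are 5'-phosphorylated so the ligase can join them to
#' an annealed forward primer across the junction.
#'
#' @name fivec-tails
#' @keywords internal
NULL

A_KEY_TAIL <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"
P1_KEY_TAIL <- "ATCACCGACTGCCCATAGAGAGG"

#' Design 5C primers over eligible restriction fragments
#'
#' Assigns at most one primer per eligible fragment under one of two
#' schemes:
#' \describe{
#'   \item{anchored}{("cluster R") reverse primers on every eligible fragment
#'     overlapping `anchor_region` (the gene cluster), forward primers on all
#'     other eligible fragments — yields a cluster-versus-region matrix.}
#'   \item{alternating}{("FR") forward and reverse primers alternate along
#'     the region in genomic order, starting with forward — yields an
#'     all-versus-all style matrix.}
#' }
#'
#' Primer cores are taken from the fragment end abutting a cut site: the
#' forward core is the last `primer_len` bases of its fragment (ending at
#' the downstream cut) and the reverse core the first `primer_len` bases
#' (starting at the upstream cut). With the cut placed at the first base of
#' the recognition site, a ligated forward+reverse junction therefore
#' contains the intact site — the property the read filters rely on.
#' Thermodynamic optimisation and genome-wide uniqueness screening are not
#' modelled; fragments to skip for such reasons are passed via `exclude`.
#' Eligible fragments shorter than `primer_len` cannot host a core and are
#' skipped with a warning.
#'
#' @param fragments `GRanges` from [filter_fragments()] (eligibility must be
#'   set).
#' @param sequence The digested sequence (character or `DNAString`); cores
#'   are extracted from it.
#' @param scheme `"anchored"` or `"alternating"`.
#' @param anchor_region `GRanges` (length 1) required for the anchored
#'   scheme; must overlap at least one eligible fragment.
#' @param primer_len Core length in nt (default 30).
#' @param exclude Integer fragment indices to skip (user-supplied exclusion
#'   list standing in for uniqueness/repeat screens).
#' @return A `FivecDesign` object: list with `scheme`, `primers`
#'   (data.frame: `primer_id`, `fragment_index`, `orientation`,
#'   `core_sequence`, `full_sequence`, `phosphorylated_5prime`), `fragments`,
#'   `region`, `anchor_region`, `primer_len`.
#' @export
design_primers <- function(fragments, sequence,
                           scheme = c("anchored", "alternating"),
                           anchor_region = NULL, primer_len = 30L,
                           exclude = integer()) {
  scheme <- match.arg(scheme)
  stopifnot(methods::is(fragments, "GRanges"))
  elig_flag <- S4Vectors::mcols(fragments)$eligible
  if (is.null(elig_flag) || anyNA(elig_flag)) {
    stop("fragment eligibility not set; run filter_fragments() first")
  }
  seq_chr <- as.character(sequence)
  if (nchar(seq_chr) < max(BiocGenerics::end(fragments))) {
    stop("'sequence' is shorter than the fragment map")
  }
  primer_len <- as.integer(primer_len)
  if (primer_len < 1L) stop("'primer_len' must be positive")

  elig <- fragments[elig_flag & !(S4Vectors::mcols(fragments)$index %in% exclude)]
  too_short <- BiocGenerics::width(elig) < primer_len
  if (any(too_short)) {
    warning(sprintf("skipping %d eligible fragment(s) shorter than primer length",
                    sum(too_short)))
    elig <- elig[!too_short]
  }
  if (length(elig) == 0L) stop("no fragments available for primer design")

  if (scheme == "anchored") {
    if (is.null(anchor_region)) {
      stop("anchored scheme requires 'anchor_region'")
    }
    stopifnot(methods::is(anchor_region, "GRanges"))
    in_anchor <- IRanges::overlapsAny(elig, anchor_region)
    if (!any(in_anchor)) {
      stop("'anchor_region' overlaps no eligible fragment")
    }
    orientation <- ifelse(in_anchor, "reverse", "forward")
  } else {
    orientation <- rep_len(c("forward", "reverse"), length(elig))
  }

  st <- BiocGenerics::start(elig)
  en <- BiocGenerics::end(elig)
  core <- ifelse(orientation == "forward",
                 substring(seq_chr, en - primer_len + 1L, en),
                 substring(seq_chr, st, st + primer_len - 1L))
  idx <- S4Vectors::mcols(elig)$index
  primers <- data.frame(
    primer_id = paste0(ifelse(orientation == "forward", "F_", "R_"), idx),
    fragment_index = idx,
    orientation = orientation,
    core_sequence = core,
    full_sequence = ifelse(orientation == "forward",
                           paste0(A_KEY_TAIL, core),
                           paste0(core, P1_KEY_TAIL)),
    phosphorylated_5prime = orientation == "reverse",
    seqnames = as.character(GenomeInfoDb::seqnames(elig)),
    start = st,
    end = en,
    stringsAsFactors = FALSE
  )

  structure(
    list(scheme = scheme, primers = primers, fragments = fragments,
         region = range(GenomicRanges::granges(fragments)),
         anchor_region = anchor_region, primer_len = primer_len),
    class = "FivecDesign"
  )
}

#' @export
print.FivecDesign <- function(x, ...) {
  n_f <- sum(x$primers$orientation == "forward")
  n_r <- sum(x$primers$orientation == "reverse")
  cat(sprintf("FivecDesign (%s scheme): %d forward / %d reverse primers\n",
              x$scheme, n_f, n_r))
  cat(sprintf("  region: %s:%d-%d\n",
              as.character(GenomeInfoDb::seqnames(x$region))[1],
              BiocGenerics::start(x$region), BiocGenerics::end(x$region)))
  invisible(x)
}

#' Enumerate junction references for a 5C design
#'
#' Builds the reference a sequencing run is mapped against: one entry per
#' (forward, reverse) primer pair, with reference sequence equal to the
#' forward core followed by the reverse core. By the primer-placement
#' convention the restriction site sits intact at the joint of every
#' reference.
#'
#' @param design A `FivecDesign`.
#' @return data.frame with `forward_id`, `reverse_id`, `sequence`;
#'   `nrow = n_forward * n_reverse`.
#' @export
junction_reference <- function(design) {
  stopifnot(methods::is(design, "FivecDesign"))
  p <- design$primers
  fwd <- p[p$orientation == "forward", , drop = FALSE]
  rev <- p[p$orientation == "reverse", , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    stop("design must contain at least one forward and one reverse primer")
  }
  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)),
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    forward_id = fwd$primer_id[grid$f],
    reverse_id = rev$primer_id[grid$r],
    sequence = paste0(fwd$core_sequence[grid$f], rev$core_sequence[grid$r]),
    stringsAsFactors = FALSE
  )
}

#' Write design primers as FASTA
#'
#' Record ids encode primer id, orientation and genomic coordinates
#' (`F_12|forward|chr:start-end`). Full sequences (core plus tail) are
#' written.
#'
#' @param design A `FivecDesign`.
#' @param path Output FASTA.
#' @export
write_primers_fasta <- function(design, path) {
  p <- design$primers
  set <- Biostrings::DNAStringSet(p$full_sequence)
  names(set) <- sprintf("%s|%s|%s:%d-%d", p$primer_id, p$orientation,
                        p$seqnames, p$start, p$end)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write the primer design table as TSV
#'
#' @param design A `FivecDesign`.
#' @param path Output TSV.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design$primers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
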