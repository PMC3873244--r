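#' Call candidate enhancers from multi-mark ChIP peak sets
#'
#' Nominates candidate enhancers from peak intervals of enhancer-associated
#' marks using a two-branch rule:
#' \describe{
#'   \item{branch A (`rnap2_plus_one`)}{an RNA-polymerase-II peak
#'     overlapping at least one peak of any other supplied mark;}
#'   \item{branch B (`p300_h3k27ac`)}{a p300 peak overlapping an H3K27Ac
#'     peak.}
#' }
#' A candidate's interval is the union (covering range) of the seed peak
#' and its directly overlapping supporting peaks, so the full evidenced
#' footprint is kept. Candidates overlapping any promoter padded by
#' `promoter_pad` bp are removed (enhancers must be distinct from proximal
#' promoters), then overlapping candidates are merged with their supporting
#' marks unioned; a merged candidate reachable through branch A is labeled
#' A. Overlap means at least one shared base pair; peak scores are not
#' thresholded here — peak significance is decided upstream by the peak
#' caller.
#'
#' @param peaksets Named list of `GRanges`, one per mark (e.g. `RNAP2`,
#'   `Med12`, `p300`, `H3K27Ac`). Must contain `rnap2_mark` or both `pair`
#'   marks.
#' @param promoters `GRanges` of promoter intervals (may be empty).
#' @param rnap2_mark Name of the RNAP2 peak set (default `"RNAP2"`).
#' @param pair Names of the co-occurrence pair (default p300 + H3K27Ac).
#' @param promoter_pad Padding in bp defining "promoter-proximal"
#'   (default 1,000, the conventional proximal-promoter window; the rule
#'   itself names no distance, so this is configurable).
#' @return `GRanges` of non-overlapping candidates with metadata columns
#'   `supporting_marks` (comma-separated), `branch` and `n_marks`.
#' @export
call_candidates <- function(peaksets, promoters = GenomicRanges::GRanges(),
                            rnap2_mark = "RNAP2",
                            pair = c("p300", "H3K27Ac"),
                            promoter_pad = 1000L) {
  if (!is.list(peaksets) || length(peaksets) == 0L) {
    stop("'peaksets' must be a non-empty named list of GRanges")
  }
  if (is.null(names(peaksets)) || any(names(peaksets) == "")) {
    stop("'peaksets' must be named by mark")
  }
  has_rnap2 <- rnap2_mark %in% names(peaksets)
  has_pair <- all(pair %in% names(peaksets))
  if (!has_rnap2 && !has_pair) {
    stop("'peaksets' must contain '", rnap2_mark, "' or both of: ",
         paste(pair, collapse = ", "))
  }

  seed_candidates <- function(seeds, support_sets, seed_mark, branch,
                              require_any = TRUE) {
    out <- list()
    for (i in seq_along(seeds)) {
      seed <- seeds[i]
      supp_marks <- character()
      pieces <- GenomicRanges::granges(seed)
      for (mk in names(support_sets)) {
        hits <- support_sets[[mk]][IRanges::overlapsAny(support_sets[[mk]], seed)]
        if (length(hits) > 0L) {
          supp_marks <- c(supp_marks, mk)
          pieces <- c(pieces, GenomicRanges::granges(hits))
        }
      }
      if (require_any && length(supp_marks) == 0L) next
      cand <- range(pieces)
      S4Vectors::mcols(cand)$supporting_marks <-
        paste(sort(unique(c(seed_mark, supp_marks))), collapse = ",")
      S4Vectors::mcols(cand)$branch <- branch
      out[[length(out) + 1L]] <- cand
    }
    if (length(out) == 0L) return(GenomicRanges::GRanges())
    do.call(c, out)
  }

  cands <- GenomicRanges::GRanges()
  if (has_rnap2) {
    others <- peaksets[setdiff(names(peaksets), rnap2_mark)]
    if (length(others) > 0L && length(peaksets[[rnap2_mark]]) > 0L) {
      cands <- c(cands, seed_candidates(peaksets[[rnap2_mark]], others,
                                        rnap2_mark, "rnap2_plus_one"))
    }
  }
  if (has_pair && length(peaksets[[pair[1]]]) > 0L) {
    cands <- c(cands,
               seed_candidates(peaksets[[pair[1]]], peaksets[pair[2]],
                               pair[1], "p300_h3k27ac"))
  }
  if (length(cands) == 0L) return(cands)

  # promoter exclusion
  if (length(promoters) > 0L) {
    pad <- GenomicRanges::resize(promoters,
                                 BiocGenerics::width(promoters) + 2L * promoter_pad,
                                 fix = "center")
    cands <- cands[!IRanges::overlapsAny(cands, pad)]
    if (length(cands) == 0L) return(cands)
  }

  # merge overlapping candidates, union marks, branch A wins
  merged <- GenomicRanges::reduce(cands, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  marks <- vapply(revmap, function(ii) {
    paste(sort(unique(unlist(strsplit(
      S4Vectors::mcols(cands)$supporting_marks[ii], ",", fixed = TRUE)))),
      collapse = ",")
  }, "")
  branch <- vapply(revmap, function(ii) {
    br <- S4Vectors::mcols(cands)$branch[ii]
    if ("rnap2_plus_one" %in% br) "rnap2_plus_one" else "p300_h3k27ac"
  }, "")
  S4Vectors::mcols(merged) <- NULL
  S4Vectors::mcols(merged)$supporting_marks <- marks
  S4Vectors::mcols(merged)$branch <- branch
  S4Vectors::mcols(merged)$n_marks <-
    lengths(strsplit(marks, ",", fixed = TRUE))
  sort(merged)
}

#' Write candidate enhancers as BED
#'
#' `name` = rule branch, `score` = number of supporting marks.
#'
#' @param candidates `GRanges` from [call_candidates()].
#' @param path Output BED.
#' @export
write_candidates_bed <- function(candidates, path) {
  gr <- GenomicRanges::granges(candidates)
  S4Vectors::mcols(gr)$name <- S4Vectors::mcols(candidates)$branch
  S4Vectors::mcols(gr)$score <- S4Vectors::mcols(candidates)$n_marks
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Load a peak table fixture (chrom, start, end per row)
#'
#' Reads supplementary-style peak tables: a TSV with `chrom`, `start`,
#' `end` columns in 1-based inclusive coordinates.
#'
#' @param path TSV file.
#' @return `GRanges`.
#' @export
read_peak_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
  GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end))
}
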