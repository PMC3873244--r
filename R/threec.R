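#' 3C interaction frequency from template and control triplicates
#'
#' Each 3C primer pair is quantified in three template (cross-linked
#' library) and three control (randomly ligated BAC library) PCR reactions.
#' Every template value is divided by every control value and the nine
#' ratios are averaged — because the BAC control contains all possible
#' ligation junctions at equimolar ratio, the per-primer-pair PCR
#' efficiency appears in both numerator and denominator and cancels.
#'
#' @param template_values Three non-negative template quantities.
#' @param control_values Three strictly positive control quantities (an
#'   equimolar BAC library cannot yield a zero control).
#' @return list with `interaction_frequency` (mean of the nine ratios),
#'   `se` (standard error of the nine ratios, `sd / 3`) and `ratios`.
#' @examples
#' compute_if(c(2, 2, 2), c(1, 1, 1))$interaction_frequency  # 2
#' @export
compute_if <- function(template_values, control_values) {
  if (length(template_values) != 3L || length(control_values) != 3L) {
    stop("exactly 3 template and 3 control values are required")
  }
  if (!is.numeric(template_values) || !is.numeric(control_values) ||
      anyNA(template_values) || anyNA(control_values)) {
    stop("template and control values must be numeric and non-missing")
  }
  if (any(template_values < 0)) stop("template values must be >= 0")
  if (any(control_values <= 0)) stop("control values must be > 0")
  ratios <- as.vector(outer(template_values, control_values, "/"))
  list(
    interaction_frequency = mean(ratios),
    se = stats::sd(ratios) / sqrt(length(ratios)),
    ratios = ratios
  )
}

#' Average 3C interaction frequencies across biological replicates
#'
#' Per-pair arithmetic mean across replicate profiles, with the standard
#' error of the mean. Replicates must cover the identical pair list. With a
#' single replicate the mean is the identity and the SEM is `NA` (a
#' one-point SEM is undefined; this convention is deliberate).
#'
#' @param replicates List (length >= 1) of data.frames with columns `pair`
#'   and `interaction_frequency`, identical `pair` vectors throughout.
#' @return data.frame with `pair`, `interaction_frequency` (mean), `sem`,
#'   `n_replicates`.
#' @export
average_replicates <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 1L) {
    stop("'replicates' must be a non-empty list")
  }
  ref_pairs <- replicates[[1]]$pair
  for (r in replicates) {
    if (!is.data.frame(r) ||
        !all(c("pair", "interaction_frequency") %in% names(r)) ||
        !identical(r$pair, ref_pairs)) {
      stop("replicates must share an identical pair list")
    }
  }
  k <- length(replicates)
  mat <- vapply(replicates, function(r) r$interaction_frequency,
                numeric(length(ref_pairs)))
  mat <- matrix(mat, nrow = length(ref_pairs))
  data.frame(
    pair = ref_pairs,
    interaction_frequency = rowMeans(mat),
    sem = if (k == 1L) NA_real_ else apply(mat, 1L, stats::sd) / sqrt(k),
    n_replicates = k,
    stringsAsFactors = FALSE
  )
}

#' Cross-library normalization factor from a control-region profile
#'
#' Different 3C libraries are put on a common scale using compaction
#' profiles over control regions (a housekeeping region such as USP22
#' and/or an intergenic region). The factor is the mean over shared pairs
#' of `reference / profile`; multiplying the library by it matches its
#' control-region level to the reference's.
#'
#' @param profile Named numeric vector (pair -> IF) for the library's
#'   control region; strictly positive.
#' @param reference_profile Named numeric vector for the reference library;
#'   strictly positive. At least 3 pairs must be shared.
#' @return Positive scale factor.
#' @export
cross_library_factor <- function(profile, reference_profile) {
  stopifnot(is.numeric(profile), is.numeric(reference_profile))
  shared <- intersect(names(profile), names(reference_profile))
  if (length(shared) < 3L) stop("fewer than 3 shared control pairs")
  p <- profile[shared]
  r <- reference_profile[shared]
  if (any(r <= 0)) stop("reference profile must be strictly positive")
  if (any(p <= 0)) stop("library profile must be strictly positive")
  mean(r / p)
}

#' Read a 3C quantification table
#'
#' TSV with columns `pair`, `t1`, `t2`, `t3`, `c1`, `c2`, `c3` (three
#' template and three BAC-control values per primer pair). Malformed rows
#' are reported by row number.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_threec_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair", "t1", "t2", "t3", "c1", "c2", "c3")
  if (!all(need %in% names(tab))) {
    stop("3C TSV must have columns: ", paste(need, collapse = ", "))
  }
  num <- tab[, need[-1]]
  bad <- which(!stats::complete.cases(num) |
                 apply(num, 1L, function(v) any(!is.finite(as.numeric(v)))))
  if (length(bad) > 0L) {
    stop("malformed 3C row ", bad[1], " (pair '", tab$pair[bad[1]], "')")
  }
  tab
}

#' Compute interaction frequencies for a whole 3C table
#'
#' Applies [compute_if()] row-wise.
#'
#' @param tab data.frame from [read_threec_tsv()].
#' @return data.frame with `pair`, `interaction_frequency`, `se`.
#' @export
threec_profile <- function(tab) {
  res <- lapply(seq_len(nrow(tab)), function(i) {
    compute_if(as.numeric(tab[i, c("t1", "t2", "t3")]),
               as.numeric(tab[i, c("c1", "c2", "c3")]))
  })
  data.frame(
    pair = tab$pair,
    interaction_frequency = vapply(res, `[[`, 0, "interaction_frequency"),
    se = vapply(res, `[[`, 0, "se"),
    stringsAsFactors = FALSE
  )
}

#' Write a 3C interaction-frequency profile as TSV
#'
#' @param profile data.frame (e.g. from [threec_profile()] or
#'   [average_replicates()]).
#' @param path Output TSV.
#' @export
write_threec_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an anchor profile as bedGraph
#'
#' Interaction frequencies keyed on the midpoints of the test fragments,
#' for plotting contact-versus-position curves from a fixed anchor.
#'
#' @param profile data.frame with `pair` and `interaction_frequency`.
#' @param test_fragments `GRanges` parallel to `profile` rows.
#' @param path Output bedGraph.
#' @export
write_anchor_bedgraph <- function(profile, test_fragments, path) {
  stopifnot(length(test_fragments) == nrow(profile))
  mids <- floor((BiocGenerics::start(test_fragments) +
                   BiocGenerics::end(test_fragments)) / 2)
  gr <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(test_fragments)),
    IRanges::IRanges(mids, width = 1L),
    score = profile$interaction_frequency
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
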