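#' Contact matrix container
#'
#' Rectangular interaction-frequency matrix with genomic axes. Rows and
#' columns carry `GRanges` (fragments or bins) sorted by genomic start;
#' `values` holds interaction frequencies with `NA` marking missing cells
#' (never silently imputed as zero). `state` tracks the processing stage:
#' `expected` (model probabilities), `raw` (read counts), `normalized`
#' (reads per 1,000 total), `binned`, `smoothed`, `differential`. Negative
#' values are only legal in the differential state.
#'
#' @param values Numeric matrix; `dimnames` name the axes (primer, fragment
#'   or bin ids).
#' @param row_ranges,col_ranges `GRanges` parallel to the rows/columns.
#' @param state Processing state.
#' @param total_run_reads Total filtered reads of the sequencing run
#'   (set by [normalize_matrix()]).
#' @param genome Genome label used in the on-disk axis labels.
#' @return A `ContactMatrix` (S3).
#' @export
contact_matrix <- function(values, row_ranges, col_ranges,
                           state = c("raw", "expected", "normalized",
                                     "binned", "smoothed", "differential"),
                           total_run_reads = NA_real_, genome = "synthetic") {
  state <- match.arg(state)
  stopifnot(is.matrix(values), is.numeric(values),
            methods::is(row_ranges, "GRanges"),
            methods::is(col_ranges, "GRanges"),
            nrow(values) == length(row_ranges),
            ncol(values) == length(col_ranges))
  if (is.unsorted(BiocGenerics::start(row_ranges)) ||
      is.unsorted(BiocGenerics::start(col_ranges))) {
    stop("axis ranges must be sorted by genomic start")
  }
  if (state != "differential" && any(values < 0, na.rm = TRUE)) {
    stop("negative interaction frequencies are only valid in the differential state")
  }
  if (is.null(names(row_ranges)) && !is.null(rownames(values))) {
    names(row_ranges) <- rownames(values)
  }
  if (is.null(names(col_ranges)) && !is.null(colnames(values))) {
    names(col_ranges) <- colnames(values)
  }
  structure(
    list(values = values, row_ranges = row_ranges, col_ranges = col_ranges,
         state = state, total_run_reads = total_run_reads, genome = genome),
    class = "ContactMatrix"
  )
}

#' @export
dim.ContactMatrix <- function(x) dim(x$values)

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix [%s]: %d x %d cells (%d missing)\n",
              x$state, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  if (!is.na(x$total_run_reads)) {
    cat(sprintf("  total run reads: %g\n", x$total_run_reads))
  }
  invisible(x)
}

#' Extract the value matrix of a ContactMatrix
#'
#' @param m A `ContactMatrix`.
#' @return Numeric matrix.
#' @export
cm_values <- function(m) m$values

axis_midpoints <- function(gr) {
  (BiocGenerics::start(gr) + BiocGenerics::end(gr)) / 2
}

same_axes <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    identical(as.character(GenomeInfoDb::seqnames(a$row_ranges)),
              as.character(GenomeInfoDb::seqnames(b$row_ranges))) &&
    identical(BiocGenerics::start(a$row_ranges), BiocGenerics::start(b$row_ranges)) &&
    identical(BiocGenerics::end(a$row_ranges), BiocGenerics::end(b$row_ranges)) &&
    identical(BiocGenerics::start(a$col_ranges), BiocGenerics::start(b$col_ranges)) &&
    identical(BiocGenerics::end(a$col_ranges), BiocGenerics::end(b$col_ranges))
}

#' Build a raw contact matrix from an interaction-frequency list
#'
#' Forward primers index the rows and reverse primers the columns, both in
#' genomic order. Designed pairs without observed reads are zero; fragments
#' without a designed primer are simply absent from the axes.
#'
#' @param records data.frame from [tally()]`$records`.
#' @param design A `FivecDesign`.
#' @param genome Genome label.
#' @return `ContactMatrix` in `raw` state.
#' @export
build_matrix <- function(records, design, genome = "synthetic") {
  stopifnot(methods::is(design, "FivecDesign"), is.data.frame(records))
  p <- design$primers
  fwd <- p[p$orientation == "forward", , drop = FALSE]
  rev <- p[p$orientation == "reverse", , drop = FALSE]
  fwd <- fwd[order(fwd$start), , drop = FALSE]
  rev <- rev[order(rev$start), , drop = FALSE]
  values <- matrix(0, nrow(fwd), nrow(rev),
                   dimnames = list(fwd$primer_id, rev$primer_id))
  if (nrow(records) > 0L) {
    ri <- match(records$forward_id, fwd$primer_id)
    ci <- match(records$reverse_id, rev$primer_id)
    if (anyNA(ri) || anyNA(ci)) {
      bad <- c(records$forward_id[is.na(ri)], records$reverse_id[is.na(ci)])
      stop("record names unknown primer(s): ", paste(unique(bad), collapse = ", "))
    }
    values[cbind(ri, ci)] <- records$raw_count
  }
  primer_ranges <- function(tab) {
    GenomicRanges::GRanges(tab$seqnames,
                           IRanges::IRanges(tab$start, tab$end))
  }
  contact_matrix(values, primer_ranges(fwd), primer_ranges(rev),
                 state = "raw", genome = genome)
}

#' Normalize a raw contact matrix to reads per thousand
#'
#' Each cell is divided by the total number of filtered reads from the
#' sequencing run and multiplied by 1,000, putting all matrices on a common
#' reads-per-thousand scale. The total includes every read passing filters
#' in the run, control-region contacts included.
#'
#' @param m `ContactMatrix` in `raw` state.
#' @param total_run_reads Positive read total of the run.
#' @return `ContactMatrix` in `normalized` state.
#' @export
normalize_matrix <- function(m, total_run_reads) {
  stopifnot(methods::is(m, "ContactMatrix"))
  if (m$state != "raw") stop("normalize_matrix() expects a raw matrix")
  if (!is.numeric(total_run_reads) || length(total_run_reads) != 1L ||
      is.na(total_run_reads) || total_run_reads <= 0) {
    stop("'total_run_reads' must be a single positive number")
  }
  m$values <- m$values * 1000 / total_run_reads
  m$state <- "normalized"
  m$total_run_reads <- total_run_reads
  m
}

bin_axis <- function(gr, bin_size, origin, stop_at) {
  mids <- axis_midpoints(gr)
  idx <- floor((mids - origin) / bin_size) + 1L
  n_bins <- max(1L, ceiling((stop_at - origin + 1) / bin_size))
  starts <- origin + (seq_len(n_bins) - 1L) * bin_size
  ends <- pmin(starts + bin_size - 1, stop_at)
  bins <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(gr))[1],
    IRanges::IRanges(starts, ends)
  )
  names(bins) <- paste0("bin_", seq_len(n_bins))
  list(bins = bins, idx = idx, n = n_bins)
}

#' Bin a contact matrix into fixed genomic windows
#'
#' Bins tile the region in `bin_size` steps from the common start of the
#' row and column axes; each fragment pair is assigned to exactly one bin
#' pair by fragment midpoints, and the bin value is the mean over its
#' non-missing assigned cells. Bin pairs receiving no cells are missing.
#' Using one origin for both axes makes the binned matrix of an
#' alternating-design run square with identical axes, as needed for
#' boundary calling.
#'
#' @param m `ContactMatrix` (`normalized` or `expected`).
#' @param bin_size Bin width in bp (default 20,000).
#' @return `ContactMatrix` in `binned` state.
#' @export
bin_matrix <- function(m, bin_size = 20000) {
  stopifnot(methods::is(m, "ContactMatrix"))
  if (!m$state %in% c("normalized", "expected")) {
    stop("bin_matrix() expects a normalized (or expected) matrix")
  }
  if (!is.numeric(bin_size) || bin_size <= 0) stop("'bin_size' must be > 0")
  origin <- min(BiocGenerics::start(m$row_ranges),
                BiocGenerics::start(m$col_ranges))
  stop_at <- max(BiocGenerics::end(m$row_ranges),
                 BiocGenerics::end(m$col_ranges))
  rb <- bin_axis(m$row_ranges, bin_size, origin, stop_at)
  cb <- bin_axis(m$col_ranges, bin_size, origin, stop_at)

  V <- m$values
  W <- !is.na(V)
  V[!W] <- 0
  A <- matrix(0, rb$n, nrow(V))
  A[cbind(rb$idx, seq_len(nrow(V)))] <- 1
  B <- matrix(0, cb$n, ncol(V))
  B[cbind(cb$idx, seq_len(ncol(V)))] <- 1
  num <- A %*% V %*% t(B)
  den <- A %*% (W * 1) %*% t(B)
  out <- num / den
  out[den == 0] <- NA_real_
  dimnames(out) <- list(names(rb$bins), names(cb$bins))
  res <- contact_matrix(out, rb$bins, cb$bins, state = "raw",
                        total_run_reads = m$total_run_reads,
                        genome = m$genome)
  res$state <- "binned"
  res
}

#' Smooth a contact matrix with a genomic-distance boxcar
#'
#' Each output cell is the mean of all non-missing input cells whose row
#' and column midpoints both lie within `window / 2` bp of the target
#' cell's midpoints (a two-dimensional uniform window; no Gaussian
#' weighting). Cells whose neighborhood is entirely missing stay missing.
#'
#' @param m `ContactMatrix` (`normalized`, `binned` or `expected`).
#' @param window Window width in bp (default 8,000).
#' @return `ContactMatrix` in `smoothed` state.
#' @export
smooth_matrix <- function(m, window = 8000) {
  stopifnot(methods::is(m, "ContactMatrix"))
  if (!m$state %in% c("normalized", "binned", "expected")) {
    stop("smooth_matrix() expects a normalized, binned or expected matrix")
  }
  if (!is.numeric(window) || window <= 0) stop("'window' must be > 0")
  rm_ <- axis_midpoints(m$row_ranges)
  cm_ <- axis_midpoints(m$col_ranges)
  Rn <- abs(outer(rm_, rm_, "-")) <= window / 2
  Cn <- abs(outer(cm_, cm_, "-")) <= window / 2
  V <- m$values
  W <- !is.na(V)
  V[!W] <- 0
  num <- Rn %*% V %*% t(Cn)
  den <- Rn %*% (W * 1) %*% t(Cn)
  out <- num / den
  out[den == 0] <- NA_real_
  dimnames(out) <- dimnames(m$values)
  m$values <- out
  m$state <- "smoothed"
  m
}

#' Subtract two contact matrices (tissue differential)
#'
#' Computes `a - b` cell-wise, e.g. limb minus head to reveal
#' tissue-enriched contacts. Both matrices must be in the same state
#' (normalized, binned or smoothed — subtracting raw counts is refused
#' because unequal sequencing depths would dominate) and on identical axes.
#' Cells missing in either input are missing in the result.
#'
#' @param a,b `ContactMatrix` objects.
#' @return `ContactMatrix` in `differential` state.
#' @export
differential_matrix <- function(a, b) {
  stopifnot(methods::is(a, "ContactMatrix"), methods::is(b, "ContactMatrix"))
  if (a$state != b$state) stop("matrices must be in the same state")
  if (!a$state %in% c("normalized", "binned", "smoothed")) {
    stop("differential requires normalized, binned or smoothed matrices; ",
         "raw counts cannot be subtracted")
  }
  if (!same_axes(a, b)) stop("matrices must share identical axes")
  a$values <- a$values - b$values
  a$state <- "differential"
  a$total_run_reads <- NA_real_
  a
}

#' Correlation between replicate contact matrices
#'
#' Pearson correlation of `log(IF + epsilon)` over the cells that are
#' non-missing in both replicates. The default `epsilon` of 1/1000 is one
#' read at the reads-per-thousand scale.
#'
#' @param a,b `ContactMatrix` objects on identical axes.
#' @param epsilon Pseudocount added before the log (default `1e-3`).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
replicate_agreement <- function(a, b, epsilon = 1e-3) {
  stopifnot(methods::is(a, "ContactMatrix"), methods::is(b, "ContactMatrix"))
  if (!same_axes(a, b)) stop("matrices must share identical axes")
  shared <- !is.na(a$values) & !is.na(b$values)
  if (sum(shared) < 3L) stop("fewer than 3 shared non-missing cells")
  stats::cor(log(a$values[shared] + epsilon), log(b$values[shared] + epsilon))
}

axis_labels <- function(gr, genome) {
  nm <- names(gr)
  if (is.null(nm)) nm <- paste0("x", seq_along(gr))
  sprintf("%s|%s|%s:%d-%d", nm, genome,
          as.character(GenomeInfoDb::seqnames(gr)),
          BiocGenerics::start(gr), BiocGenerics::end(gr))
}

parse_axis_labels <- function(labels) {
  m <- regmatches(labels,
                  regexec("^([^|]+)\\|([^|]+)\\|([^:]+):([0-9]+)-([0-9]+)$",
                          labels))
  bad <- vapply(m, length, 0L) != 6L
  if (any(bad)) stop("malformed axis label: ", labels[bad][1])
  gr <- GenomicRanges::GRanges(
    vapply(m, `[`, "", 4L),
    IRanges::IRanges(as.integer(vapply(m, `[`, "", 5L)),
                     as.integer(vapply(m, `[`, "", 6L)))
  )
  names(gr) <- vapply(m, `[`, "", 2L)
  list(ranges = gr, genome = vapply(m, `[`, "", 3L)[1])
}

#' Write a contact matrix as TSV
#'
#' Tab-separated matrix mirroring the supplementary-table dialect: the
#' first row and column hold axis labels of the form
#' `name|genome|chrom:start-end` (1-based inclusive coordinates), cell
#' values are at the reads-per-thousand scale, and missing cells are `NA`.
#' Round-trips through [read_contact_matrix()] losslessly to at least six
#' significant digits.
#'
#' @param m `ContactMatrix`.
#' @param path Output TSV.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(methods::is(m, "ContactMatrix"))
  vals <- format(m$values, digits = 15, trim = TRUE, scientific = TRUE)
  vals[is.na(m$values)] <- "NA"
  out <- rbind(c("", axis_labels(m$col_ranges, m$genome)),
               cbind(axis_labels(m$row_ranges, m$genome), vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contact matrix from TSV
#'
#' @param path TSV written by [write_contact_matrix()].
#' @param state Processing state to stamp on the object (the dialect does
#'   not record it; default `"normalized"`).
#' @param total_run_reads Optional run total.
#' @return `ContactMatrix`.
#' @export
read_contact_matrix <- function(path, state = "normalized",
                                total_run_reads = NA_real_) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  col_ax <- parse_axis_labels(as.character(tab[1, -1]))
  row_ax <- parse_axis_labels(tab[-1, 1])
  vals <- as.matrix(tab[-1, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(names(row_ax$ranges), names(col_ax$ranges))
  m <- contact_matrix(vals, row_ax$ranges, col_ax$ranges, state = "raw",
                      total_run_reads = total_run_reads,
                      genome = row_ax$genome)
  m$state <- state
  m
}
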