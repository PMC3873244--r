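# Fixture builders used across the suite. All randomness is seeded by the
# caller; nothing here touches the global RNG state unguarded.

# string of length n that cannot contain GAATTC (alphabet lacks T)
siteless <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# sequence whose digest yields fragments of exactly the given widths
# (cut-at-site-start convention: fragments 2..k begin with GAATTC)
seq_with_fragment_widths <- function(widths, seed = 1) {
  stopifnot(widths[1] >= 1, all(widths[-1] >= 6))
  withr::with_seed(seed, {
    parts <- c(siteless(widths[1]),
               vapply(widths[-1],
                      function(w) paste0("GAATTC", siteless(w - 6)), ""))
  })
  paste(parts, collapse = "")
}

# small ready-made design: fragments of the given widths, all eligible,
# alternating or anchored primers
tiny_design <- function(widths = rep(60, 6), scheme = "alternating",
                        anchor_frags = NULL, seed = 1) {
  s <- seq_with_fragment_widths(widths, seed = seed)
  frags <- filter_fragments(digest(s), min_len = 1)
  anchor <- NULL
  if (!is.null(anchor_frags)) {
    anchor <- range(GenomicRanges::granges(frags[anchor_frags]))
  }
  list(sequence = s, fragments = frags,
       design = design_primers(frags, s, scheme, anchor_region = anchor))
}

# random ContactMatrix over synthetic fragment axes with optional missing
# cells; row/col fragments tile [1, n*step] in uneven widths
random_cm <- function(nr, nc, seed, state = "normalized", p_na = 0,
                      step = 5000) {
  withr::with_seed(seed, {
    rw <- sort(sample.int(nr * step, nr))
    cw <- sort(sample.int(nc * step, nc))
    row_r <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
      start = c(1, head(rw, -1) + 1), end = rw))
    col_r <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
      start = c(1, head(cw, -1) + 1), end = cw))
    v <- matrix(stats::runif(nr * nc, 0, 10), nr, nc,
                dimnames = list(paste0("r", 1:nr), paste0("c", 1:nc)))
    if (p_na > 0) v[stats::runif(nr * nc) < p_na] <- NA
  })
  m <- contact_matrix(v, row_r, col_r, state = "raw")
  m$state <- state
  m
}

# brute-force per-bin mean (independent binning oracle)
oracle_bin <- function(m, bin_size) {
  mid <- function(gr) (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
  origin <- min(GenomicRanges::start(m$row_ranges),
                GenomicRanges::start(m$col_ranges))
  stop_at <- max(GenomicRanges::end(m$row_ranges),
                 GenomicRanges::end(m$col_ranges))
  rb <- floor((mid(m$row_ranges) - origin) / bin_size) + 1
  cb <- floor((mid(m$col_ranges) - origin) / bin_size) + 1
  nb <- max(1, ceiling((stop_at - origin + 1) / bin_size))
  out <- matrix(NA_real_, nb, nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      cells <- m$values[rb == i, cb == j]
      if (length(cells) > 0 && any(!is.na(cells))) {
        out[i, j] <- mean(cells, na.rm = TRUE)
      }
    }
  }
  out
}

# brute-force 2-D boxcar mean (independent smoothing oracle)
oracle_smooth <- function(m, window) {
  mid <- function(gr) (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
  rm_ <- mid(m$row_ranges); cm_ <- mid(m$col_ranges)
  nr <- nrow(m$values); nc <- ncol(m$values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rows <- which(abs(rm_ - rm_[i]) <= window / 2)
      cols <- which(abs(cm_ - cm_[j]) <= window / 2)
      cells <- m$values[rows, cols]
      if (any(!is.na(cells))) out[i, j] <- mean(cells, na.rm = TRUE)
    }
  }
  out
}

# boundary precision/recall of calls against planted bin indices
boundary_pr <- function(calls, truth_bins, tol = 1) {
  tp_calls <- vapply(calls$boundary,
                     function(x) any(abs(x - truth_bins) <= tol), TRUE)
  found <- vapply(truth_bins,
                  function(t) any(abs(calls$boundary - t) <= tol), TRUE)
  c(tp = sum(tp_calls), n_calls = nrow(calls),
    found = sum(found), n_truth = length(truth_bins))
}

gr1 <- function(start, end, seq_name = "chrT") {
  GenomicRanges::GRanges(seq_name, IRanges::IRanges(start, end))
}

# single locus at [1000, 1400] carrying peaks for the marks flagged present
locus_peaksets <- function(present) {
  marks <- c("RNAP2", "Med12", "p300", "H3K27Ac")
  sets <- list()
  for (mk in marks) {
    gr <- GenomicRanges::GRanges()
    if (present[mk]) gr <- gr1(1000, 1400)
    sets[[mk]] <- gr
  }
  sets
}
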