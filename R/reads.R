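#' Map junction reads against a 5C reference set
#'
#' Deterministic stand-in for an external aligner: each read is assigned to
#' the unique reference it matches, allowing its start to fall up to
#' `max_scan` nt into the reference (the reported `offset`) and up to
#' `max_mismatch` substitutions. Reads matching zero or more than one
#' reference within tolerance stay unmapped. A read of length `L` can align
#' at offset `k` against a reference of length `L + k` (i.e. the read equals
#' the reference with its first `k` bases dropped, up to substitutions).
#'
#' Exact matches are resolved by hashed lookup per offset; the substitution
#' search first narrows candidates by the forward-core prefix and only then
#' falls back to a full scan, so mapping stays fast at simulated-run scale.
#'
#' @param reads data.frame with at least a `sequence` column (other columns
#'   pass through).
#' @param references data.frame from [junction_reference()].
#' @param max_scan Maximum start offset in nt (default 5).
#' @param max_mismatch Maximum substitutions (default 2).
#' @return `reads` with `forward_id`, `reverse_id` and `offset` columns
#'   added (`NA` for unmapped reads).
#' @export
map_reads <- function(reads, references, max_scan = 5L, max_mismatch = 2L) {
  stopifnot(is.data.frame(reads), is.data.frame(references),
            all(c("forward_id", "reverse_id", "sequence") %in% names(references)))
  max_scan <- as.integer(max_scan)
  max_mismatch <- as.integer(max_mismatch)
  n <- nrow(reads)
  reads$forward_id <- rep(NA_character_, n)
  reads$reverse_id <- rep(NA_character_, n)
  reads$offset <- rep(NA_integer_, n)
  if (n == 0L || nrow(references) == 0L) return(reads)

  ref_seq <- references$sequence
  ref_len <- nchar(ref_seq)
  read_seq <- reads$sequence
  read_len <- nchar(read_seq)

  n_hits <- integer(n)        # exact-match candidate count per read
  hit_ref <- integer(n)       # last matching reference row
  hit_off <- integer(n)

  for (k in 0:max_scan) {
    suff <- substring(ref_seq, k + 1L)
    dup <- duplicated(suff) | duplicated(suff, fromLast = TRUE)
    cand <- which(read_len > 0L & (read_len + k) %in% unique(ref_len))
    if (length(cand) == 0L) next
    m <- match(read_seq[cand], suff)
    ok <- !is.na(m)
    if (!any(ok)) next
    ci <- cand[ok]
    mi <- m[ok]
    # length must agree (match() alone ignores ref length groups)
    good <- read_len[ci] == ref_len[mi] - k
    ci <- ci[good]; mi <- mi[good]
    if (length(ci) == 0L) next
    amb <- dup[mi]
    n_hits[ci] <- n_hits[ci] + ifelse(amb, 2L, 1L)
    hit_ref[ci] <- mi
    hit_off[ci] <- k
  }

  mapped <- n_hits == 1L
  reads$forward_id[mapped] <- references$forward_id[hit_ref[mapped]]
  reads$reverse_id[mapped] <- references$reverse_id[hit_ref[mapped]]
  reads$offset[mapped] <- hit_off[mapped]

  # substitution fallback for reads with no exact hit
  todo <- which(n_hits == 0L)
  if (length(todo) > 0L && max_mismatch > 0L) {
    # prefix index: references sharing a forward core share their first
    # primer_len bases; any prefix shorter than the full reference works
    pre_len <- max(1L, min(ref_len) %/% 2L)
    ref_raw <- lapply(ref_seq, charToRaw)
    prefix_of <- function(k) substring(ref_seq, k + 1L, k + pre_len)
    for (i in todo) {
      L <- read_len[i]
      xr <- charToRaw(read_seq[i])
      found <- 0L; f_ref <- 0L; f_off <- 0L
      for (k in 0:max_scan) {
        rows <- which(ref_len == L + k)
        if (length(rows) == 0L) next
        if (L >= pre_len) {
          hit_pre <- which(substr(read_seq[i], 1L, pre_len) == prefix_of(k)[rows])
          scan_rows <- if (length(hit_pre) > 0L) rows[hit_pre] else rows
        } else {
          scan_rows <- rows
        }
        for (r in scan_rows) {
          mm <- sum(ref_raw[[r]][(k + 1L):(L + k)] != xr)
          if (mm <= max_mismatch) {
            found <- found + 1L
            f_ref <- r; f_off <- k
            if (found > 1L) break
          }
        }
        if (found > 1L) break
      }
      if (found == 1L) {
        reads$forward_id[i] <- references$forward_id[f_ref]
        reads$reverse_id[i] <- references$reverse_id[f_ref]
        reads$offset[i] <- f_off
      }
    }
  }
  reads
}

#' Filter mapped junction reads
#'
#' Applies the three read-level filters of a 5C sequencing run: reads are
#' kept iff mapped, with quality at least `min_quality`, start offset within
#' `max_offset` nt of the reference start, and containing the restriction
#' site. Rejected reads are tallied by the first failing rule, checked in
#' the order quality, (unmapped), offset, site; offset is only defined for
#' mapped reads, hence the placement of the unmapped class.
#'
#' @param reads Mapped reads from [map_reads()] (columns `sequence`,
#'   `quality`, `offset`, `forward_id`, `reverse_id`).
#' @param min_quality Minimum mapping-quality score (default 30; reads with
#'   quality below this are removed).
#' @param max_offset Maximum absolute alignment offset in nt (default 2;
#'   reads aligning more than this far from the reference start are
#'   removed).
#' @param site Restriction site that must be present in the read sequence
#'   (default EcoRI).
#' @return list with `kept` (data.frame of retained reads), `rejected`
#'   (named integer vector: `quality`, `offset`, `site`, `unmapped`) and
#'   `n_input`. `kept` rows plus the rejection tally always partition the
#'   input.
#' @export
filter_reads <- function(reads, min_quality = 30L, max_offset = 2L,
                         site = ECORI_SITE) {
  stopifnot(is.data.frame(reads),
            all(c("sequence", "quality") %in% names(reads)))
  if (min_quality < 0L) stop("'min_quality' must be >= 0")
  if (max_offset < 0L) stop("'max_offset' must be >= 0")
  n <- nrow(reads)
  if (!"offset" %in% names(reads)) reads$offset <- rep(NA_integer_, n)
  if (!"forward_id" %in% names(reads)) reads$forward_id <- rep(NA_character_, n)
  mapped <- !is.na(reads$forward_id)

  reason <- rep(NA_character_, n)
  low_q <- reads$quality < min_quality
  reason[low_q] <- "quality"
  sel <- is.na(reason) & !mapped
  reason[sel] <- "unmapped"
  sel <- is.na(reason) & abs(reads$offset) > max_offset
  reason[sel] <- "offset"
  has_site <- grepl(site, reads$sequence, fixed = TRUE)
  sel <- is.na(reason) & !has_site
  reason[sel] <- "site"

  kept <- reads[is.na(reason), , drop = FALSE]
  rejected <- vapply(c("quality", "offset", "site", "unmapped"),
                     function(r) sum(reason == r, na.rm = TRUE), integer(1))
  list(kept = kept, rejected = rejected, n_input = n)
}

#' Tally kept reads into an interaction-frequency list
#'
#' Counts read multiplicity per (forward, reverse) primer pair. The sum of
#' raw counts equals the number of reads used, and the tally is invariant
#' under read order.
#'
#' @param kept data.frame of mapped, filtered reads.
#' @return list with `records` (data.frame: `forward_id`, `reverse_id`,
#'   `raw_count`, sorted by ids) and `total_used_reads`.
#' @export
tally <- function(kept) {
  stopifnot(is.data.frame(kept))
  if (nrow(kept) == 0L) {
    return(list(records = data.frame(forward_id = character(),
                                     reverse_id = character(),
                                     raw_count = integer(),
                                     stringsAsFactors = FALSE),
                total_used_reads = 0L))
  }
  if (anyNA(kept$forward_id) || anyNA(kept$reverse_id)) {
    stop("all tallied reads must be mapped")
  }
  key <- paste(kept$forward_id, kept$reverse_id, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  records <- data.frame(
    forward_id = vapply(parts, `[`, "", 1L),
    reverse_id = vapply(parts, `[`, "", 2L),
    raw_count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  records <- records[order(records$forward_id, records$reverse_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  list(records = records, total_used_reads = nrow(kept))
}

#' Write an interaction-frequency list as TSV
#'
#' @param records data.frame from [tally()]`$records`.
#' @param path Output TSV.
#' @export
write_ifl_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
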