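#' Parameters of the synthetic contact model
#'
#' Bundles the planted truth for simulation: a region with restriction
#' sites laid down by a Poisson point process, a contact model with
#' power-law distance decay `(d + d0)^-alpha`, multiplicative attenuation
#' for crossing TAD (`cross_tad_multiplier`) and sub-TAD
#' (`cross_subtad_multiplier`) boundaries, focal tissue-specific contacts
#' with enrichment `gamma`, read-level contaminant classes planted at exact
#' counts, and annotation positions for promoters and enhancers.
#'
#' @param region_length Region size in bp (>= 50 kb).
#' @param site_density Expected restriction sites per kb.
#' @param decay_exponent Distance-decay exponent `alpha` (> 0, or 0 for a
#'   flat model).
#' @param decay_offset Decay offset `d0` in bp (> 0, keeps the short-range
#'   expectation finite).
#' @param tad_boundaries TAD boundary positions in bp, strictly increasing.
#' @param subtad_boundaries Sub-TAD boundary positions in bp, strictly
#'   increasing.
#' @param cross_tad_multiplier Attenuation per TAD boundary crossed, in
#'   (0, 1).
#' @param cross_subtad_multiplier Attenuation per sub-TAD boundary crossed,
#'   in (`cross_tad_multiplier`, 1].
#' @param specific_contacts data.frame with columns `start_a`, `end_a`,
#'   `start_b`, `end_b`, `gamma` (> 1), `tissue`; fragment pairs hitting
#'   interval A on one side and interval B on the other are enriched
#'   `gamma`-fold in the matching tissue.
#' @param contamination Named rates `low_quality`, `offset_shift`,
#'   `site_ablated`; must sum below 1.
#' @param n_reads Default sequencing depth.
#' @param promoter_positions,enhancer_positions Annotation midpoints in bp.
#' @param anchor_start,anchor_end Anchor region (gene cluster) for the
#'   anchored 5C scheme.
#' @param seed Default seed.
#' @return A `ContactModelParams` (validated list).
#' @export
contact_model_params <- function(region_length = 1e6,
                                 site_density = 0.25,
                                 decay_exponent = 1,
                                 decay_offset = 5000,
                                 tad_boundaries = numeric(),
                                 subtad_boundaries = numeric(),
                                 cross_tad_multiplier = 0.3,
                                 cross_subtad_multiplier = 0.6,
                                 specific_contacts = NULL,
                                 contamination = c(low_quality = 0,
                                                   offset_shift = 0,
                                                   site_ablated = 0),
                                 n_reads = 1e5,
                                 promoter_positions = numeric(),
                                 enhancer_positions = numeric(),
                                 anchor_start = NA_real_,
                                 anchor_end = NA_real_,
                                 seed = 1L) {
  stopifnot(region_length > 0, site_density >= 0,
            decay_exponent >= 0, decay_offset > 0, n_reads >= 1)
  if (!(cross_tad_multiplier > 0 && cross_tad_multiplier < 1)) {
    stop("'cross_tad_multiplier' must lie in (0, 1)")
  }
  if (!(cross_subtad_multiplier > cross_tad_multiplier &&
        cross_subtad_multiplier <= 1)) {
    stop("'cross_subtad_multiplier' must lie in (cross_tad_multiplier, 1]")
  }
  if (is.unsorted(tad_boundaries, strictly = TRUE) ||
      is.unsorted(subtad_boundaries, strictly = TRUE)) {
    stop("boundary positions must be strictly increasing")
  }
  need <- c("low_quality", "offset_shift", "site_ablated")
  if (!all(need %in% names(contamination))) {
    stop("'contamination' must name rates: ", paste(need, collapse = ", "))
  }
  contamination <- contamination[need]
  if (any(contamination < 0) || sum(contamination) >= 1) {
    stop("contamination rates must be >= 0 and sum below 1")
  }
  if (!is.null(specific_contacts)) {
    stopifnot(is.data.frame(specific_contacts),
              all(c("start_a", "end_a", "start_b", "end_b", "gamma",
                    "tissue") %in% names(specific_contacts)),
              all(specific_contacts$gamma > 1))
  }
  structure(
    list(region_length = region_length, site_density = site_density,
         decay_exponent = decay_exponent, decay_offset = decay_offset,
         tad_boundaries = tad_boundaries,
         subtad_boundaries = subtad_boundaries,
         cross_tad_multiplier = cross_tad_multiplier,
         cross_subtad_multiplier = cross_subtad_multiplier,
         specific_contacts = specific_contacts,
         contamination = contamination, n_reads = n_reads,
         promoter_positions = promoter_positions,
         enhancer_positions = enhancer_positions,
         anchor_start = anchor_start, anchor_end = anchor_end,
         seed = as.integer(seed)),
    class = "ContactModelParams"
  )
}

#' @export
print.ContactModelParams <- function(x, ...) {
  cat(sprintf(paste0("ContactModelParams: %g bp, %.3g sites/kb, ",
                     "alpha=%g, d0=%g\n"),
              x$region_length, x$site_density, x$decay_exponent,
              x$decay_offset))
  cat(sprintf("  %d TAD / %d sub-TAD boundaries, %d specific contact(s)\n",
              length(x$tad_boundaries), length(x$subtad_boundaries),
              if (is.null(x$specific_contacts)) 0L
              else nrow(x$specific_contacts)))
  invisible(x)
}

#' Demonstration scenario: a HoxA-like regulatory landscape
#'
#' A 1-Mb region emulating the qualitative architecture around a Hox
#' cluster and its upstream regulatory landscape: a 10-gene cluster at the
#' 3' end of the region split by a TAD boundary (3' genes in one TAD, 5'
#' genes extending into the other), two enhancer-rich sub-TADs upstream,
#' and six enhancer-promoter contacts present in "limb" and absent in
#' "head". Restriction-site density of 0.25/kb gives a ~4-kb mean fragment,
#' matching the resolution of an EcoRI 5C design. Contamination rates
#' (1.2% low-quality, 0.8% offset-shifted, 0.5% site-ablated) give the
#' planted 120/80/50 contaminants in a 10,000-read run.
#'
#' @param n_reads Sequencing depth per tissue (default 1e6).
#' @param seed Scenario seed.
#' @return `ContactModelParams`.
#' @export
mini_hoxa_params <- function(n_reads = 1e6, seed = 20240L) {
  enh <- c(350e3, 430e3, 510e3, 650e3, 720e3, 790e3)
  prom <- seq(810e3, 990e3, by = 20e3)
  targets <- prom[prom > 880e3]
  contact_model_params(
    region_length = 1e6,
    site_density = 0.25,
    decay_exponent = 1,
    decay_offset = 5000,
    tad_boundaries = 880e3,
    subtad_boundaries = c(300e3, 600e3, 800e3),
    cross_tad_multiplier = 0.3,
    cross_subtad_multiplier = 0.6,
    specific_contacts = data.frame(
      start_a = enh - 2000, end_a = enh + 2000,
      start_b = targets - 2000, end_b = targets + 2000,
      gamma = 5, tissue = "limb",
      stringsAsFactors = FALSE
    ),
    contamination = c(low_quality = 0.012, offset_shift = 0.008,
                      site_ablated = 0.005),
    n_reads = n_reads,
    promoter_positions = prom,
    enhancer_positions = enh,
    anchor_start = 800e3 + 1, anchor_end = 1e6,
    seed = seed
  )
}

# index of the eligible fragment containing each position (nearest by
# midpoint when the containing fragment is ineligible)
snap_to_eligible <- function(pos, frags) {
  mids <- axis_midpoints(frags)
  st <- BiocGenerics::start(frags)
  en <- BiocGenerics::end(frags)
  vapply(pos, function(p) {
    cont <- which(st <= p & en >= p)
    if (length(cont) == 1L) cont else which.min(abs(mids - p))
  }, 0L)
}

# annotation intervals centered in their host fragments, clipped to the
# fragment so each annotation overlaps exactly one (eligible) fragment
positions_to_annotations <- function(pos, frags, half_width, prefix,
                                     seq_name) {
  if (length(pos) == 0L) {
    return(list(gr = GenomicRanges::GRanges(), frag_idx = integer(),
                mid = numeric()))
  }
  i <- snap_to_eligible(pos, frags)
  mid <- round(axis_midpoints(frags))[i]
  gr <- GenomicRanges::GRanges(
    seq_name,
    IRanges::IRanges(pmax(BiocGenerics::start(frags)[i], mid - half_width),
                     pmin(BiocGenerics::end(frags)[i], mid + half_width))
  )
  S4Vectors::mcols(gr)$name <- paste0(prefix, seq_along(gr))
  list(gr = gr, frag_idx = i, mid = mid)
}

#' Simulate a region with planted restriction sites and annotations
#'
#' Generates a random A/C/G/T sequence, plants restriction-site occurrences
#' by a seeded Poisson point process at `site_density` and scrubs every
#' accidental occurrence elsewhere, so that [digest()] reproduces the
#' planted fragment map exactly. Promoter and enhancer annotations are
#' placed on eligible fragments nearest the requested positions (1 kb
#' intervals clipped to the host fragment), and specific-contact intervals
#' are snapped to their host fragments so every planted contact is
#' probe-able; the returned `params` reflect the snapped coordinates and
#' must be used for downstream [expected_matrix()] calls.
#'
#' @param params `ContactModelParams`.
#' @param seed Seed (defaults to `params$seed`).
#' @param seq_name Sequence name.
#' @return list with `sequence` (character), `fragments` (eligibility-set
#'   `GRanges`), `promoters`, `enhancers`, `site_positions` and `params`.
#' @export
simulate_region <- function(params, seed = params$seed,
                            seq_name = "chrS") {
  stopifnot(methods::is(params, "ContactModelParams"))
  if (params$region_length < 50e3) {
    stop("'region_length' must be at least 50 kb")
  }
  L <- as.integer(params$region_length)
  site <- ECORI_SITE
  site_chars <- strsplit(site, "")[[1]]
  k <- length(site_chars)

  withr::with_seed(seed, {
    n_sites <- stats::rpois(1L, params$site_density * L / 1000)
    pos <- sort(sample.int(L - k - 1L, min(n_sites, L %/% (2L * k))) + 1L)
    if (length(pos) > 1L) {
      pos <- pos[c(TRUE, diff(pos) >= k)]
    }
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (p in pos) seqv[p:(p + k - 1L)] <- site_chars

    # scrub accidental occurrences (site cannot overlap a planted copy)
    seq_chr <- paste(seqv, collapse = "")
    repeat {
      occ <- BiocGenerics::start(
        Biostrings::matchPattern(site, Biostrings::DNAString(seq_chr)))
      spurious <- setdiff(occ, pos)
      if (length(spurious) == 0L) break
      seqv[spurious + 2L] <- "C"
      seq_chr <- paste(seqv, collapse = "")
    }
  })

  fragments <- filter_fragments(digest(seq_chr, site, seq_name = seq_name))
  if (all(BiocGenerics::width(fragments) < 100)) {
    stop("site density too high: all fragments are below 100 bp")
  }
  elig <- fragments[S4Vectors::mcols(fragments)$eligible]
  proms <- positions_to_annotations(params$promoter_positions, elig, 500L,
                                    "gene", seq_name)
  enhs <- positions_to_annotations(params$enhancer_positions, elig, 500L,
                                   "enh", seq_name)

  # snap specific-contact intervals onto their host eligible fragments so
  # every planted contact is probed by a primer pair
  sc <- params$specific_contacts
  if (!is.null(sc) && nrow(sc) > 0L) {
    ia <- snap_to_eligible((sc$start_a + sc$end_a) / 2, elig)
    ib <- snap_to_eligible((sc$start_b + sc$end_b) / 2, elig)
    sc$start_a <- BiocGenerics::start(elig)[ia]
    sc$end_a <- BiocGenerics::end(elig)[ia]
    sc$start_b <- BiocGenerics::start(elig)[ib]
    sc$end_b <- BiocGenerics::end(elig)[ib]
    params$specific_contacts <- sc
  }
  params$promoter_positions <- proms$mid
  params$enhancer_positions <- enhs$mid

  list(
    sequence = seq_chr,
    fragments = fragments,
    promoters = proms$gr,
    enhancers = enhs$gr,
    site_positions = pos,
    params = params
  )
}

#' Expected contact matrix of the generative model
#'
#' Expected interaction probability for every ordered pair of eligible
#' fragments:
#' `E[i, j]` is proportional to `(d_ij + d0)^-alpha` times
#' `beta_T^(TAD boundaries crossed)` times
#' `beta_S^(sub-TAD boundaries crossed)`, times `gamma` for pairs hitting a
#' specific contact whose tissue matches, normalized to sum to one.
#' Distances and boundary crossings are evaluated at fragment midpoints.
#'
#' @param fragments Eligibility-set `GRanges` (from [simulate_region()]).
#' @param params `ContactModelParams`.
#' @param tissue Tissue tag selecting which specific contacts apply.
#' @return Square symmetric `ContactMatrix` in `expected` state over
#'   eligible fragments.
#' @export
expected_matrix <- function(fragments, params, tissue = "limb") {
  stopifnot(methods::is(params, "ContactModelParams"),
            methods::is(fragments, "GRanges"))
  elig_flag <- S4Vectors::mcols(fragments)$eligible
  if (is.null(elig_flag) || anyNA(elig_flag)) {
    stop("fragment eligibility not set; run filter_fragments() first")
  }
  frags <- fragments[elig_flag]
  mid <- axis_midpoints(frags)
  n <- length(frags)
  D <- abs(outer(mid, mid, "-"))
  E <- (D + params$decay_offset)^(-params$decay_exponent)

  crossings <- function(bounds) {
    ct <- matrix(0, n, n)
    for (b in bounds) {
      left <- mid < b
      ct <- ct + outer(left, left, FUN = function(x, y) as.numeric(xor(x, y)))
    }
    ct
  }
  if (length(params$tad_boundaries) > 0L) {
    E <- E * params$cross_tad_multiplier^crossings(params$tad_boundaries)
  }
  if (length(params$subtad_boundaries) > 0L) {
    E <- E * params$cross_subtad_multiplier^crossings(params$subtad_boundaries)
  }
  sc <- params$specific_contacts
  if (!is.null(sc)) {
    sc <- sc[sc$tissue == tissue, , drop = FALSE]
    seq_name <- as.character(GenomeInfoDb::seqnames(frags))[1]
    for (i in seq_len(nrow(sc))) {
      ia <- IRanges::overlapsAny(
        frags, GenomicRanges::GRanges(seq_name,
                                      IRanges::IRanges(sc$start_a[i], sc$end_a[i])))
      ib <- IRanges::overlapsAny(
        frags, GenomicRanges::GRanges(seq_name,
                                      IRanges::IRanges(sc$start_b[i], sc$end_b[i])))
      mask <- outer(ia, ib, "&") | outer(ib, ia, "&")
      E[mask] <- E[mask] * sc$gamma[i]
    }
  }
  E <- E / sum(E)
  ids <- paste0("f", S4Vectors::mcols(frags)$index)
  dimnames(E) <- list(ids, ids)
  ax <- GenomicRanges::granges(frags)
  names(ax) <- ids
  m <- contact_matrix(E, ax, ax, state = "raw", genome = "synthetic")
  m$state <- "expected"
  m
}

#' Restrict an expected matrix to the pairs probed by a 5C design
#'
#' A 5C run only observes (forward, reverse) primer pairs, so reads are
#' drawn from the expected model restricted to those cells and
#' renormalized. Rows become forward primers and columns reverse primers.
#'
#' @param expected Symmetric fragment-level `ContactMatrix` from
#'   [expected_matrix()].
#' @param design A `FivecDesign` over the same fragments.
#' @return `ContactMatrix` in `expected` state with primer axes.
#' @export
expected_for_design <- function(expected, design) {
  stopifnot(methods::is(expected, "ContactMatrix"),
            methods::is(design, "FivecDesign"),
            expected$state == "expected")
  p <- design$primers
  fwd <- p[p$orientation == "forward", , drop = FALSE]
  rev <- p[p$orientation == "reverse", , drop = FALSE]
  fwd <- fwd[order(fwd$start), , drop = FALSE]
  rev <- rev[order(rev$start), , drop = FALSE]
  ri <- match(paste0("f", fwd$fragment_index), rownames(expected$values))
  ci <- match(paste0("f", rev$fragment_index), colnames(expected$values))
  if (anyNA(ri) || anyNA(ci)) {
    stop("design includes fragments absent from the expected matrix")
  }
  V <- expected$values[ri, ci, drop = FALSE]
  V <- V / sum(V)
  dimnames(V) <- list(fwd$primer_id, rev$primer_id)
  gr <- function(tab) {
    g <- GenomicRanges::GRanges(tab$seqnames,
                                IRanges::IRanges(tab$start, tab$end))
    names(g) <- tab$primer_id
    g
  }
  m <- contact_matrix(V, gr(fwd), gr(rev), state = "raw",
                      genome = expected$genome)
  m$state <- "expected"
  m
}

#' Sample read-pair counts from an expected matrix
#'
#' Draws `n_reads` pair identities multinomially from the expected cell
#' probabilities and returns the raw count matrix — the exact distribution
#' a contamination-free sequencing run produces, without materializing
#' read sequences.
#'
#' @param expected `ContactMatrix` in `expected` state.
#' @param n_reads Number of reads.
#' @param seed Seed.
#' @return `ContactMatrix` in `raw` state with `total_run_reads = n_reads`.
#' @export
simulate_counts <- function(expected, n_reads, seed) {
  stopifnot(methods::is(expected, "ContactMatrix"),
            expected$state == "expected", n_reads > 0)
  p <- as.vector(expected$values)
  p[is.na(p)] <- 0
  counts <- withr::with_seed(seed,
                             stats::rmultinom(1L, as.integer(n_reads), p))
  V <- matrix(as.numeric(counts), nrow(expected$values),
              ncol(expected$values), dimnames = dimnames(expected$values))
  contact_matrix(V, expected$row_ranges, expected$col_ranges,
                 state = "raw", total_run_reads = as.numeric(n_reads),
                 genome = expected$genome)
}

#' Simulate junction reads at read level, with planted contaminants
#'
#' Draws pair identities multinomially from a design-restricted expected
#' matrix, then materializes reads: clean reads carry the exact junction
#' reference sequence, a quality of at least 30 and zero start offset.
#' Exact planted counts of three contaminant classes (not per-read
#' Bernoulli draws, so filter tests can assert exact tallies) are applied
#' to disjoint read subsets:
#' \itemize{
#'   \item `low_quality`: quality drawn below 30;
#'   \item `offset_shift`: first 3-5 nt of the sequence removed;
#'   \item `site_ablated`: the restriction site destroyed by one
#'     substitution.
#' }
#'
#' @param expected Primer-axis `ContactMatrix` from
#'   [expected_for_design()].
#' @param design The `FivecDesign` (for junction references).
#' @param params `ContactModelParams` (contamination rates).
#' @param n_reads Number of reads (default `params$n_reads`).
#' @param seed Seed.
#' @return list with `reads` (data.frame: `sequence`, `quality`,
#'   `true_forward`, `true_reverse`, `class`) and `contamination_counts`.
#' @export
simulate_reads <- function(expected, design, params,
                           n_reads = params$n_reads, seed = params$seed) {
  stopifnot(methods::is(expected, "ContactMatrix"),
            expected$state == "expected",
            methods::is(design, "FivecDesign"))
  refs <- junction_reference(design)
  key <- paste(refs$forward_id, refs$reverse_id, sep = "\r")
  n_reads <- as.integer(n_reads)
  rates <- params$contamination
  n_classes <- round(rates * n_reads)

  withr::with_seed(seed, {
    p <- as.vector(expected$values)
    p[is.na(p)] <- 0
    counts <- stats::rmultinom(1L, n_reads, p)[, 1L]
    cell <- rep.int(seq_along(p), counts)
    cell <- sample(cell)  # random read order
    fid <- rownames(expected$values)[(cell - 1L) %% nrow(expected$values) + 1L]
    rid <- colnames(expected$values)[(cell - 1L) %/% nrow(expected$values) + 1L]
    seqs <- refs$sequence[match(paste(fid, rid, sep = "\r"), key)]
    qual <- sample(30:40, n_reads, replace = TRUE)
    class <- rep("clean", n_reads)

    idx <- seq_len(sum(n_classes))
    stopifnot(length(idx) <= n_reads)
    cls_of <- rep(names(n_classes), n_classes)
    pick <- sample.int(n_reads, length(idx))

    lowq <- pick[cls_of == "low_quality"]
    qual[lowq] <- sample(0:29, length(lowq), replace = TRUE)
    class[lowq] <- "low_quality"

    shift <- pick[cls_of == "offset_shift"]
    k <- sample(3:5, length(shift), replace = TRUE)
    seqs[shift] <- substring(seqs[shift], k + 1L)
    class[shift] <- "offset_shift"

    abl <- pick[cls_of == "site_ablated"]
    for (i in abl) {
      at <- regexpr(ECORI_SITE, seqs[i], fixed = TRUE)
      substr(seqs[i], at + 2L, at + 2L) <- "C"  # GAATTC -> GACTTC
    }
    class[abl] <- "site_ablated"
  })

  list(
    reads = data.frame(sequence = seqs, quality = qual,
                       true_forward = fid, true_reverse = rid,
                       class = class, stringsAsFactors = FALSE),
    contamination_counts = n_classes
  )
}

#' Simulate ChIP peak sets over planted enhancers and promoters
#'
#' Every planted enhancer emits a peak for each mark independently with
#' probability `1 - dropout[mark]`; promoters emit RNAP2 peaks; decoy
#' peaks are added uniformly at a background rate. The per-enhancer truth
#' table is returned for recall scoring.
#'
#' @param enhancers,promoters `GRanges` from [simulate_region()].
#' @param region_length Region size in bp.
#' @param marks Mark names (default RNAP2, Med12, p300, H3K27Ac).
#' @param dropout Named per-mark dropout probabilities (default 0).
#' @param background Expected decoy peaks per mark (Poisson; default 0).
#' @param seed Seed.
#' @param seq_name Sequence name.
#' @return list with `peaks` (named list of sorted `GRanges`) and `truth`
#'   (logical enhancer x mark matrix).
#' @export
simulate_chip <- function(enhancers, promoters, region_length,
                          marks = c("RNAP2", "Med12", "p300", "H3K27Ac"),
                          dropout = stats::setNames(numeric(length(marks)), marks),
                          background = 0, seed = 1L, seq_name = "chrS") {
  stopifnot(all(marks %in% names(dropout)))
  withr::with_seed(seed, {
    truth <- matrix(FALSE, length(enhancers), length(marks),
                    dimnames = list(
                      if (length(enhancers)) S4Vectors::mcols(enhancers)$name,
                      marks))
    peaks <- stats::setNames(vector("list", length(marks)), marks)
    centers <- if (length(enhancers)) axis_midpoints(enhancers) else numeric()
    mk_peaks <- function(ctr, wid) {
      if (length(ctr) == 0L) return(GenomicRanges::GRanges())
      GenomicRanges::GRanges(
        seq_name,
        IRanges::IRanges(pmax(1, round(ctr - wid / 2)),
                         pmin(region_length, round(ctr + wid / 2))))
    }
    for (mk in marks) {
      emit <- if (length(enhancers))
        stats::runif(length(enhancers)) >= dropout[[mk]] else logical()
      truth[, mk] <- emit
      gr <- mk_peaks(centers[emit] + stats::runif(sum(emit), -100, 100),
                     stats::runif(sum(emit), 400, 800))
      if (mk == "RNAP2" && length(promoters) > 0L) {
        gr <- c(gr, mk_peaks(axis_midpoints(promoters), 600))
      }
      n_decoy <- stats::rpois(1L, background)
      if (n_decoy > 0L) {
        gr <- c(gr, mk_peaks(stats::runif(n_decoy, 1, region_length), 500))
      }
      peaks[[mk]] <- sort(gr)
    }
  })
  list(peaks = peaks, truth = truth)
}

#' Simulate 3C template/control triplicates with primer-efficiency bias
#'
#' Emulates gel-quantified PCR against an equimolar BAC control: the
#' control expectation per pair is the primer-pair efficiency bias alone,
#' the template expectation is bias times the true contact frequency.
#' Triplicates are drawn log-normally around the expectation with
#' coefficient of variation `cv` (log-normal keeps quantities positive).
#'
#' @param true_contacts Named numeric vector of true contact frequencies
#'   per primer pair.
#' @param biases Named numeric vector of per-pair efficiency biases
#'   (same names).
#' @param cv Coefficient of variation of the PCR noise (default 0.1).
#' @param seed Seed.
#' @return data.frame with `pair`, `t1..t3`, `c1..c3`; the truth is
#'   attached as attribute `"truth"`.
#' @export
simulate_3c <- function(true_contacts, biases, cv = 0.1, seed = 1L) {
  stopifnot(is.numeric(true_contacts), is.numeric(biases),
            identical(names(true_contacts), names(biases)),
            all(biases > 0), all(true_contacts >= 0), cv >= 0)
  n <- length(true_contacts)
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mu) {
    if (cv == 0) return(mu)
    mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  withr::with_seed(seed, {
    tmpl <- vapply(1:3, function(i) draw(biases * true_contacts), numeric(n))
    ctrl <- vapply(1:3, function(i) draw(biases), numeric(n))
  })
  out <- data.frame(pair = names(true_contacts),
                    t1 = tmpl[, 1], t2 = tmpl[, 2], t3 = tmpl[, 3],
                    c1 = ctrl[, 1], c2 = ctrl[, 2], c3 = ctrl[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- true_contacts
  out
}
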