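#' Write a provenance record for an output directory
#'
#' JSON recording the parameters of a run and MD5 checksums of its input
#' files, so any artifact can be traced to the exact inputs and settings
#' that produced it. Deliberately contains no timestamps: reruns with
#' identical inputs produce byte-identical provenance.
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters.
#' @param inputs Character vector of input file paths.
#' @export
write_provenance <- function(path, params, inputs = character()) {
  sums <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else list()
  jsonlite::write_json(list(parameters = params, input_md5 = sums),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Materialize a full synthetic scenario directory
#'
#' Runs the generator end to end and writes every input the 5C pipeline
#' consumes: region FASTA, fragment/promoter/enhancer/anchor BED files,
#' per-tissue junction-read TSVs (read level, with planted contaminants)
#' and a `truth.json` with the planted structure.
#'
#' @param params `ContactModelParams` (e.g. [mini_hoxa_params()]).
#' @param out_dir Output directory (created if needed).
#' @param tissues Tissues to simulate reads for (default limb and head).
#' @param n_reads Reads per tissue (default `params$n_reads`).
#' @param scheme 5C scheme used for the read simulation.
#' @param seed Base seed; per-tissue read seeds are derived from it.
#' @return Invisible named list of written paths.
#' @export
simulate_scenario <- function(params, out_dir,
                              tissues = c("limb", "head"),
                              n_reads = params$n_reads,
                              scheme = "anchored", seed = params$seed) {
  stopifnot(methods::is(params, "ContactModelParams"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  region <- simulate_region(params, seed = seed)
  params <- region$params  # annotation/contact coordinates after snapping
  seq_name <- as.character(GenomeInfoDb::seqnames(region$fragments))[1]

  paths <- list(
    fasta = file.path(out_dir, "region.fa"),
    fragments = file.path(out_dir, "fragments.bed"),
    promoters = file.path(out_dir, "promoters.bed"),
    enhancers = file.path(out_dir, "enhancers.bed"),
    anchor = file.path(out_dir, "anchor.bed"),
    truth = file.path(out_dir, "truth.json")
  )
  write_region_fasta(region$sequence, paths$fasta, name = seq_name)
  write_fragments_bed(region$fragments, paths$fragments)
  write_bed(region$promoters, paths$promoters)
  write_bed(region$enhancers, paths$enhancers)

  anchor <- NULL
  if (!is.na(params$anchor_start)) {
    anchor <- GenomicRanges::GRanges(
      seq_name, IRanges::IRanges(params$anchor_start, params$anchor_end))
    write_bed(anchor, paths$anchor)
  }

  design <- design_primers(region$fragments, region$sequence,
                           scheme = scheme, anchor_region = anchor)
  contamination <- list()
  for (i in seq_along(tissues)) {
    tissue <- tissues[i]
    exp_frag <- expected_matrix(region$fragments, params, tissue = tissue)
    exp_des <- expected_for_design(exp_frag, design)
    sim <- simulate_reads(exp_des, design, params, n_reads = n_reads,
                          seed = seed + i)
    p <- file.path(out_dir, sprintf("reads_%s.tsv", tissue))
    write_reads_tsv(sim$reads, p)
    paths[[paste0("reads_", tissue)]] <- p
    contamination[[tissue]] <- as.list(sim$contamination_counts)
  }

  jsonlite::write_json(
    list(
      seed = seed, n_reads = n_reads, scheme = scheme,
      site_positions = region$site_positions,
      tad_boundaries = params$tad_boundaries,
      subtad_boundaries = params$subtad_boundaries,
      specific_contacts = params$specific_contacts,
      contamination_counts = contamination
    ),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

default_5c_config <- function() {
  list(site = ECORI_SITE, min_quality = 30L, max_offset = 2L,
       max_scan = 5L, max_mismatch = 2L, primer_len = 30L,
       min_len = 100L, max_len = 20000L,
       bin_size = 20000, smooth_window = 8000,
       smooth_input = "normalized",
       window_bins = 3L, min_prominence = 1.5,
       scheme = "anchored")
}

validate_5c_config <- function(config) {
  cfg <- utils::modifyList(default_5c_config(), config)
  if (is.null(cfg$fasta) || is.null(cfg$reads) || is.null(cfg$out_dir)) {
    stop("config must provide 'fasta', 'reads' and 'out_dir'")
  }
  if (cfg$min_quality < 0) stop("'min_quality' must be >= 0")
  if (cfg$max_offset < 0) stop("'max_offset' must be >= 0")
  if (cfg$bin_size <= 0 || cfg$smooth_window <= 0) {
    stop("'bin_size' and 'smooth_window' must be > 0")
  }
  missing <- c(cfg$fasta, unlist(cfg$reads), cfg$anchor_bed)
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  cfg
}

#' Run the 5C heatmap pipeline
#'
#' Executes the full 5C analysis on one region: digestion and fragment
#' eligibility, primer design, read mapping, filtering and tallying per
#' tissue, matrix building and reads-per-thousand normalization, binning
#' and smoothing, tissue subtraction when two or more tissues are given,
#' and insulation boundary calling when the binned matrix is square. All
#' artifacts are written under `config$out_dir` together with a
#' provenance JSON; nothing mutates the inputs, and a rerun with the same
#' inputs is byte-identical.
#'
#' @param config Named list. Required: `fasta` (region FASTA), `reads`
#'   (named list/vector tissue -> reads TSV), `out_dir`. Optional:
#'   `anchor_bed` (required for the anchored scheme), `scheme`, `site`,
#'   `min_quality`, `max_offset`, `max_scan`, `max_mismatch`,
#'   `primer_len`, `min_len`, `max_len`, `bin_size`, `smooth_window`,
#'   `smooth_input` (`"normalized"` to smooth the fragment-level matrix,
#'   `"binned"` to smooth after binning), `window_bins`, `min_prominence`.
#' @return Invisible list with the per-tissue matrices, the differential
#'   matrix (or `NULL`), boundary calls (or `NULL`) and written paths.
#' @export
run_5c <- function(config) {
  cfg <- validate_5c_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  seqs <- read_region_fasta(cfg$fasta)
  fragments <- filter_fragments(digest(seqs), max_len = cfg$max_len,
                                min_len = cfg$min_len)
  anchor <- if (!is.null(cfg$anchor_bed)) read_bed(cfg$anchor_bed) else NULL
  design <- design_primers(fragments, seqs[[1L]], scheme = cfg$scheme,
                           anchor_region = anchor,
                           primer_len = cfg$primer_len)
  refs <- junction_reference(design)

  tissues <- names(cfg$reads)
  if (is.null(tissues)) stop("'reads' must be named by tissue")
  matrices <- list()
  paths <- list()
  filter_stats <- list()
  for (tissue in tissues) {
    reads <- read_reads_tsv(cfg$reads[[tissue]])
    mapped <- map_reads(reads, refs, max_scan = cfg$max_scan,
                        max_mismatch = cfg$max_mismatch)
    flt <- filter_reads(mapped, min_quality = cfg$min_quality,
                        max_offset = cfg$max_offset, site = cfg$site)
    tl <- tally(flt$kept)
    filter_stats[[tissue]] <- list(rejected = as.list(flt$rejected),
                                   used = tl$total_used_reads,
                                   input = flt$n_input)
    raw <- build_matrix(tl$records, design)
    norm <- normalize_matrix(raw, tl$total_used_reads)
    binned <- bin_matrix(norm, bin_size = cfg$bin_size)
    smoothed <- smooth_matrix(
      if (identical(cfg$smooth_input, "binned")) binned else norm,
      window = cfg$smooth_window)
    matrices[[tissue]] <- list(normalized = norm, binned = binned,
                               smoothed = smoothed)
    for (st in c("normalized", "binned", "smoothed")) {
      p <- file.path(cfg$out_dir, sprintf("matrix_%s_%s.tsv", tissue, st))
      write_contact_matrix(matrices[[tissue]][[st]], p)
      paths[[paste(tissue, st, sep = "_")]] <- p
    }
  }

  diff <- NULL
  if (length(tissues) >= 2L) {
    diff <- differential_matrix(matrices[[tissues[1]]]$normalized,
                                matrices[[tissues[2]]]$normalized)
    p <- file.path(cfg$out_dir,
                   sprintf("differential_%s_minus_%s.tsv",
                           tissues[1], tissues[2]))
    write_contact_matrix(diff, p)
    paths$differential <- p
  }

  calls <- NULL
  b1 <- matrices[[tissues[1]]]$binned
  if (nrow(b1$values) == ncol(b1$values) &&
      identical(BiocGenerics::start(b1$row_ranges),
                BiocGenerics::start(b1$col_ranges)) &&
      cfg$window_bins < nrow(b1$values)) {
    profile <- insulation_profile(b1, window_bins = cfg$window_bins)
    calls <- call_boundaries(profile, min_prominence = cfg$min_prominence)
    paths$insulation <- file.path(cfg$out_dir, "insulation.bedGraph")
    write_insulation_bedgraph(profile, b1, paths$insulation)
    paths$domains <- file.path(cfg$out_dir, "domains.bed")
    write_bed(boundaries_to_domains(b1, calls), paths$domains)
  }

  paths$provenance <- file.path(cfg$out_dir, "provenance.json")
  write_provenance(
    paths$provenance,
    params = c(cfg[setdiff(names(cfg), c("reads", "out_dir"))],
               list(reads = as.list(cfg$reads)),
               list(filter_stats = filter_stats)),
    inputs = c(cfg$fasta, unlist(cfg$reads), cfg$anchor_bed))

  invisible(list(design = design, matrices = matrices, differential = diff,
                 boundaries = calls, paths = paths))
}

#' Run the 3C anchor-profile pipeline
#'
#' Computes nine-ratio interaction frequencies for each library, rescales
#' libraries to a common reference using control-region pairs, and
#' averages replicate libraries.
#'
#' @param config Named list. Required: `libraries` (named list/vector
#'   library -> 3C TSV path), `out_dir`. Optional: `control_pairs`
#'   (pair ids of the control/compaction region), `reference` (library
#'   name to normalize against; default the first) and
#'   `replicate_groups` (named list group -> library names to average).
#' @return Invisible list with per-library profiles, normalization
#'   factors, averaged groups and written paths.
#' @export
run_3c <- function(config) {
  if (is.null(config$libraries) || is.null(config$out_dir)) {
    stop("config must provide 'libraries' and 'out_dir'")
  }
  libs <- config$libraries
  missing <- unlist(libs)[!file.exists(unlist(libs))]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  profiles <- lapply(libs, function(p) threec_profile(read_threec_tsv(p)))
  factors <- stats::setNames(rep(1, length(libs)), names(libs))
  ref_name <- if (is.null(config$reference)) names(libs)[1] else config$reference
  if (!is.null(config$control_pairs) && length(libs) > 1L) {
    ref_prof <- profiles[[ref_name]]
    ref_vec <- stats::setNames(ref_prof$interaction_frequency, ref_prof$pair)
    ref_vec <- ref_vec[names(ref_vec) %in% config$control_pairs]
    for (nm in names(libs)) {
      if (nm == ref_name) next
      pr <- profiles[[nm]]
      vec <- stats::setNames(pr$interaction_frequency, pr$pair)
      vec <- vec[names(vec) %in% config$control_pairs]
      factors[[nm]] <- cross_library_factor(vec, ref_vec)
      profiles[[nm]]$interaction_frequency <-
        profiles[[nm]]$interaction_frequency * factors[[nm]]
    }
  }

  paths <- list()
  for (nm in names(libs)) {
    paths[[nm]] <- file.path(config$out_dir, sprintf("if_%s.tsv", nm))
    write_threec_profile(profiles[[nm]], paths[[nm]])
  }

  averaged <- NULL
  if (!is.null(config$replicate_groups)) {
    averaged <- lapply(config$replicate_groups, function(members) {
      average_replicates(profiles[members])
    })
    for (g in names(averaged)) {
      paths[[paste0("avg_", g)]] <- file.path(config$out_dir,
                                              sprintf("if_avg_%s.tsv", g))
      write_threec_profile(averaged[[g]], paths[[paste0("avg_", g)]])
    }
  }

  paths$provenance <- file.path(config$out_dir, "provenance.json")
  write_provenance(paths$provenance,
                   params = list(reference = ref_name,
                                 factors = as.list(factors),
                                 control_pairs = config$control_pairs),
                   inputs = unlist(libs))
  invisible(list(profiles = profiles, factors = factors,
                 averaged = averaged, paths = paths))
}
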