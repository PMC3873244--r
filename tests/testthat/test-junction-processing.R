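make_refs <- function() junction_reference(tiny_design(rep(60, 6), "alternating")$design)

test_that("reads map exactly, with truncation offsets, or not at all", {
  refs <- make_refs()
  reads <- data.frame(
    sequence = c(refs$sequence[1],                 # exact
                 substring(refs$sequence[4], 4),   # 3 nt truncated
                 siteless(60, seed = 1)),          # matches nothing
    quality = c(35L, 35L, 35L))
  out <- map_reads(reads, refs)
  expect_equal(out$offset, c(0L, 3L, NA))
  expect_equal(out$forward_id[1:2], refs$forward_id[c(1, 4)])
  expect_equal(out$reverse_id[1:2], refs$reverse_id[c(1, 4)])
  expect_true(is.na(out$forward_id[3]))
})

test_that("mapping tolerates substitutions up to the mismatch budget", {
  refs <- make_refs()
  two_mm <- refs$sequence[2]
  substr(two_mm, 5, 5) <- "N"
  substr(two_mm, 50, 50) <- "N"
  three_mm <- refs$sequence[2]
  for (pos in c(5, 15, 50)) substr(three_mm, pos, pos) <- "N"
  out <- map_reads(data.frame(sequence = c(two_mm, three_mm),
                              quality = c(35L, 35L)), refs)
  expect_equal(out$forward_id[1], refs$forward_id[2])
  expect_equal(out$offset[1], 0L)
  expect_true(is.na(out$forward_id[2]))
})

test_that("offsets beyond max_scan are not mapped", {
  refs <- make_refs()
  out <- map_reads(data.frame(sequence = substring(refs$sequence[1], 7),
                              quality = 35L), refs, max_scan = 5)
  expect_true(is.na(out$forward_id))
})

test_that("filter_reads applies quality, offset and site rules at their boundaries", {
  base <- "AAAGAATTCAAA"
  no_site <- "AAACCCCCCAAA"
  reads <- data.frame(
    sequence = c(base, base, base, no_site, base, no_site),
    quality  = c(29L, 30L, 30L, 40L, 30L, 10L),
    offset   = c(0L, 3L, 2L, 0L, 0L, 5L),
    forward_id = "F_1", reverse_id = "R_2")
  out <- filter_reads(reads)
  # quality 29 -> quality; offset 3 -> offset; offset 2 kept; no site -> site;
  # clean kept; quality 10 beats the other failures
  expect_equal(out$rejected,
               c(quality = 2L, offset = 1L, site = 1L, unmapped = 0L))
  expect_equal(nrow(out$kept), 2L)
  expect_equal(out$kept$quality, c(30L, 30L))
  # partition invariant
  expect_equal(nrow(out$kept) + sum(out$rejected), nrow(reads))
})

test_that("unmapped reads are rejected even at high quality", {
  reads <- data.frame(sequence = c("GAATTCAA", "GAATTCAA"),
                      quality = c(40L, 20L),
                      offset = c(NA_integer_, NA_integer_),
                      forward_id = c(NA_character_, NA_character_),
                      reverse_id = c(NA_character_, NA_character_))
  out <- filter_reads(reads)
  expect_equal(unname(out$rejected[c("unmapped", "quality")]), c(1L, 1L))
  expect_equal(nrow(out$kept), 0L)
})

test_that("raising min_quality never increases the kept count", {
  refs <- make_refs()
  withr::with_seed(42, {
    reads <- data.frame(
      sequence = sample(refs$sequence, 200, replace = TRUE),
      quality = sample(0:45, 200, replace = TRUE))
  })
  mapped <- map_reads(reads, refs)
  kept <- vapply(c(0, 10, 20, 30, 40, 46),
                 function(q) nrow(filter_reads(mapped, min_quality = q)$kept),
                 0)
  expect_true(all(diff(kept) <= 0))
})

test_that("tally counts pair multiplicities and ignores read order", {
  reads <- data.frame(
    sequence = "x", quality = 35L,
    forward_id = c("F1", "F1", "F1", "F2"),
    reverse_id = c("R1", "R1", "R1", "R1"))
  tl <- tally(reads)
  expect_equal(tl$total_used_reads, 4L)
  expect_equal(tl$records$raw_count[tl$records$forward_id == "F1"], 3L)
  expect_equal(tl$records$raw_count[tl$records$forward_id == "F2"], 1L)
  expect_equal(sum(tl$records$raw_count), tl$total_used_reads)

  perm <- tally(reads[c(3, 1, 4, 2), ])
  expect_identical(perm$records, tl$records)

  empty <- tally(reads[0, ])
  expect_equal(empty$total_used_reads, 0L)
  expect_equal(nrow(empty$records), 0L)
})

test_that("simulated contaminant classes are rejected exactly, by reason", {
  fx <- tiny_design(rep(80, 10), "alternating", seed = 11)
  frags <- fx$fragments
  params <- contact_model_params(
    region_length = 50e3, site_density = 0,
    contamination = c(low_quality = 0.05, offset_shift = 0.03,
                      site_ablated = 0.02),
    n_reads = 1000, seed = 5)
  # expected model over this tiny fragment set, uniform-ish
  em <- expected_matrix(filter_fragments(frags, min_len = 1), params)
  ed <- expected_for_design(em, fx$design)
  sim <- simulate_reads(ed, fx$design, params, n_reads = 1000, seed = 6)
  expect_equal(unname(sim$contamination_counts),
               c(50, 30, 20))
  refs <- junction_reference(fx$design)
  mapped <- map_reads(sim$reads, refs)
  out <- filter_reads(mapped)
  expect_equal(unname(out$rejected[c("quality", "offset", "site")]),
               c(50L, 30L, 20L))
  expect_equal(nrow(out$kept), 900L)
  # every kept read maps back to its true planted pair
  expect_equal(out$kept$forward_id, out$kept$true_forward)
  expect_equal(out$kept$reverse_id, out$kept$true_reverse)
})
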