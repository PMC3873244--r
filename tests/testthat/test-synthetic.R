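test_that("simulate_region plants sites that digest reproduces exactly", {
  p <- contact_model_params(region_length = 60e3, site_density = 0.2,
                            seed = 101)
  reg <- simulate_region(p)
  # digest boundaries = planted cut positions
  expect_equal(GenomicRanges::start(reg$fragments),
               c(1, reg$site_positions))
  expect_equal(length(reg$fragments), length(reg$site_positions) + 1L)
  # no accidental sites anywhere else
  occ <- gregexpr("GAATTC", reg$sequence, fixed = TRUE)[[1]]
  expect_setequal(as.integer(occ), reg$site_positions)
  # determinism
  reg2 <- simulate_region(p)
  expect_identical(reg$sequence, reg2$sequence)
  expect_equal(reg$site_positions, reg2$site_positions)
})

test_that("zero site density yields a single fragment and small regions error", {
  p <- contact_model_params(region_length = 50e3, site_density = 0, seed = 1)
  reg <- simulate_region(p)
  expect_equal(length(reg$fragments), 1L)
  tiny <- contact_model_params(region_length = 10e3, seed = 1)
  expect_error(simulate_region(tiny), "50 kb")
})

test_that("parameter validation enforces the model's ranges", {
  expect_error(contact_model_params(cross_tad_multiplier = 1.2), "0, 1")
  expect_error(contact_model_params(cross_tad_multiplier = 0.5,
                                    cross_subtad_multiplier = 0.4),
               "cross_tad_multiplier")
  expect_error(contact_model_params(tad_boundaries = c(3e5, 2e5)),
               "increasing")
  expect_error(contact_model_params(
    contamination = c(low_quality = 0.6, offset_shift = 0.5,
                      site_ablated = 0)), "sum below 1")
  expect_error(contact_model_params(
    specific_contacts = data.frame(start_a = 1, end_a = 2, start_b = 3,
                                   end_b = 4, gamma = 0.5, tissue = "limb")))
})

test_that("expected_matrix matches the closed-form product on a 4-fragment example", {
  # fragments of width 10 kb tiling 40 kb; one boundary at 20 kb; one
  # limb-specific contact between fragment 1 and fragment 4 with gamma 3
  s <- seq_with_fragment_widths(rep(10e3, 4), seed = 111)
  frags <- filter_fragments(digest(s, seq_name = "chrS"))
  p <- contact_model_params(region_length = 40e3, decay_exponent = 1,
                            decay_offset = 5000,
                            tad_boundaries = 20e3,
                            cross_tad_multiplier = 0.5,
                            specific_contacts = data.frame(
                              start_a = 1, end_a = 10e3,
                              start_b = 30001, end_b = 40e3,
                              gamma = 3, tissue = "limb"),
                            seed = 1)
  em <- expected_matrix(frags, p, tissue = "limb")
  mids <- (GenomicRanges::start(frags) + GenomicRanges::end(frags)) / 2
  raw <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    d <- abs(mids[i] - mids[j])
    v <- (d + 5000)^-1
    if (xor(mids[i] < 20e3, mids[j] < 20e3)) v <- v * 0.5
    if ((i == 1 && j == 4) || (i == 4 && j == 1)) v <- v * 3
    raw[i, j] <- v
  }
  expect_equal(unname(cm_values(em)), raw / sum(raw), tolerance = 1e-12)
  # head tissue: no specific enrichment
  eh <- cm_values(expected_matrix(frags, p, tissue = "head"))
  raw_h <- raw; raw_h[1, 4] <- raw_h[1, 4] / 3; raw_h[4, 1] <- raw_h[4, 1] / 3
  expect_equal(unname(eh), raw_h / sum(raw_h), tolerance = 1e-12)
})

test_that("expected_matrix decays monotonely and is flat in the alpha->0 limit", {
  p <- contact_model_params(region_length = 200e3, site_density = 0.25,
                            decay_exponent = 0, seed = 121)
  reg <- simulate_region(p)
  flat <- cm_values(expected_matrix(reg$fragments, reg$params))
  expect_lt(diff(range(flat)), 1e-15)
  p2 <- contact_model_params(region_length = 200e3, site_density = 0.25,
                             decay_exponent = 1.2, seed = 121)
  reg2 <- simulate_region(p2)
  e2 <- cm_values(expected_matrix(reg2$fragments, reg2$params))
  expect_true(all(diff(e2[1, ]) <= 1e-15))  # row 1: distance grows with j
  expect_equal(sum(e2), 1)
})

test_that("sampled pair frequencies converge to the expected matrix", {
  p <- contact_model_params(region_length = 150e3, site_density = 0.2,
                            tad_boundaries = 75e3, seed = 131)
  reg <- simulate_region(p)
  em <- expected_matrix(reg$fragments, reg$params)
  n <- 1e6
  counts <- cm_values(simulate_counts(em, n, seed = 132))
  expect_equal(sum(counts), n)
  # chi-square goodness of fit over cells pooled to expected count >= 5
  e <- as.vector(cm_values(em)) * n
  o <- as.vector(counts)
  big <- e >= 5
  o_pooled <- c(o[big], sum(o[!big]))
  e_pooled <- c(e[big], sum(e[!big]))
  keep <- e_pooled > 0
  gof <- suppressWarnings(
    stats::chisq.test(o_pooled[keep], p = e_pooled[keep] / sum(e_pooled[keep])))
  expect_gt(gof$p.value, 0.01)
  # per-cell deviations on covered cells stay within multinomial
  # concentration (|z| < 5 across all such cells)
  well <- e >= 50
  expect_lt(max(abs(o[well] - e[well]) / sqrt(e[well])), 5)
})

test_that("simulate_reads is deterministic and plants exact contaminant counts", {
  fx <- tiny_design(rep(80, 8), "alternating", seed = 141)
  params <- contact_model_params(
    region_length = 50e3, site_density = 0,
    contamination = c(low_quality = 0.02, offset_shift = 0.01,
                      site_ablated = 0.01),
    n_reads = 500, seed = 142)
  em <- expected_matrix(fx$fragments, params)
  ed <- expected_for_design(em, fx$design)
  s1 <- simulate_reads(ed, fx$design, params, seed = 143)
  s2 <- simulate_reads(ed, fx$design, params, seed = 143)
  expect_identical(s1$reads, s2$reads)
  expect_equal(unname(s1$contamination_counts), c(10, 5, 5))
  expect_equal(as.integer(table(s1$reads$class)[c("low_quality",
                                                  "offset_shift",
                                                  "site_ablated")]),
               c(10L, 5L, 5L))
  # clean reads carry intact junctions
  clean <- s1$reads[s1$reads$class == "clean", ]
  expect_true(all(grepl("GAATTC", clean$sequence, fixed = TRUE)))
  expect_true(all(clean$quality >= 30))
})

test_that("simulate_chip retains truth and zero dropout gives full recall", {
  p <- mini_hoxa_params()
  reg <- simulate_region(contact_model_params(
    region_length = 1e6, site_density = 0.25,
    promoter_positions = p$promoter_positions,
    enhancer_positions = p$enhancer_positions, seed = 151))
  chip <- simulate_chip(reg$enhancers, reg$promoters, 1e6, seed = 152)
  expect_true(all(chip$truth))
  cands <- call_candidates(chip$peaks, promoters = reg$promoters)
  hit <- IRanges::overlapsAny(reg$enhancers, cands)
  expect_true(all(hit))
  # determinism
  chip2 <- simulate_chip(reg$enhancers, reg$promoters, 1e6, seed = 152)
  expect_identical(lapply(chip2$peaks, GenomicRanges::start),
                   lapply(chip$peaks, GenomicRanges::start))
  # full dropout of partners and no co-peaks: the rule is unsatisfiable
  drop <- stats::setNames(c(0, 1, 1, 1), c("RNAP2", "Med12", "p300", "H3K27Ac"))
  chip3 <- simulate_chip(reg$enhancers, GenomicRanges::GRanges(), 1e6,
                         dropout = drop, seed = 153)
  expect_equal(length(call_candidates(chip3$peaks)), 0L)
})

test_that("simulate_3c with no bias and no noise returns the truth exactly", {
  truth <- stats::setNames(c(1.5, 0.7, 2.2), paste0("p", 1:3))
  tab <- simulate_3c(truth, stats::setNames(rep(1, 3), names(truth)),
                     cv = 0, seed = 161)
  prof <- threec_profile(tab)
  expect_equal(prof$interaction_frequency, unname(truth))
  expect_equal(prof$se, rep(0, 3))
})
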