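test_that("build_matrix fills designed pairs and rejects unknown primers", {
  fx <- tiny_design(rep(60, 4), "alternating")
  ids <- fx$design$primers$primer_id
  f_ids <- ids[fx$design$primers$orientation == "forward"]
  r_ids <- ids[fx$design$primers$orientation == "reverse"]
  empty <- build_matrix(data.frame(forward_id = character(),
                                   reverse_id = character(),
                                   raw_count = integer()), fx$design)
  expect_equal(dim(empty), c(2L, 2L))
  expect_true(all(cm_values(empty) == 0))

  rec <- data.frame(forward_id = f_ids[1], reverse_id = r_ids[1],
                    raw_count = 3L)
  m <- build_matrix(rec, fx$design)
  expect_equal(cm_values(m)[f_ids[1], r_ids[1]], 3)
  expect_equal(sum(cm_values(m)), 3)

  bad <- data.frame(forward_id = "F_99", reverse_id = r_ids[1], raw_count = 1L)
  expect_error(build_matrix(bad, fx$design), "unknown primer")
})

test_that("normalization is reads-per-thousand and conserves totals", {
  m <- random_cm(6, 5, seed = 1, state = "raw")
  m$values <- round(m$values * 10)
  n <- normalize_matrix(m, 10000)
  # spot formula: 5 reads / 10,000 total -> 0.5 at the x10^3 scale
  m2 <- m; m2$values[2, 2] <- 5
  expect_equal(cm_values(normalize_matrix(m2, 10000))[2, 2], 0.5)
  # conservation
  expect_equal(sum(cm_values(n)) * 10000 / 1000, sum(cm_values(m)),
               tolerance = 1e-12)
  # scale invariance: doubling counts and total changes nothing
  d <- m; d$values <- d$values * 2
  expect_equal(cm_values(normalize_matrix(d, 20000)), cm_values(n))
  expect_error(normalize_matrix(m, 0), "positive")
  expect_error(normalize_matrix(n, 10), "raw")
})

test_that("binning equals the brute-force per-bin mean", {
  for (seed in 1:8) {
    m <- random_cm(8, 7, seed = seed, p_na = 0.2)
    b <- bin_matrix(m, 10000)
    expect_equal(unname(cm_values(b)), oracle_bin(m, 10000),
                 tolerance = 1e-12)
  }
  # two fragment pairs in one bin pair average; single pair passes through
  m <- contact_matrix(matrix(c(1, 3), 2, 1,
                             dimnames = list(c("a", "b"), "c")),
                      gr1(c(1, 501), c(500, 1000)), gr1(1, 900),
                      state = "raw")
  m$state <- "normalized"
  b <- bin_matrix(m, 2000)
  expect_equal(unname(cm_values(b)[1, 1]), 2)
  expect_error(bin_matrix(m, 0), "bin_size")
})

test_that("smoothing equals the brute-force boxcar mean", {
  for (seed in 1:8) {
    m <- random_cm(7, 6, seed = seed + 100, p_na = 0.15)
    s <- smooth_matrix(m, 12000)
    expect_equal(unname(cm_values(s)), oracle_smooth(m, 12000),
                 tolerance = 1e-12)
  }
  # constant matrix unchanged; tiny window is the identity
  cmat <- contact_matrix(matrix(2, 4, 4), gr1(c(1, 101, 201, 301) * 100,
                                              c(100, 200, 300, 400) * 100),
                         gr1(c(1, 101, 201, 301) * 100,
                             c(100, 200, 300, 400) * 100), state = "raw")
  cmat$state <- "normalized"
  expect_true(all(cm_values(smooth_matrix(cmat, 5000)) == 2))
  m2 <- random_cm(5, 5, seed = 9)
  expect_equal(cm_values(smooth_matrix(m2, 2)), cm_values(m2))
  expect_error(smooth_matrix(m2, -1), "window")
})

test_that("bin and smooth stay within the input range and preserve missingness", {
  m <- random_cm(9, 9, seed = 77, p_na = 0.3)
  for (out in list(bin_matrix(m, 15000), smooth_matrix(m, 20000))) {
    v <- cm_values(out)
    expect_gte(min(v, na.rm = TRUE), min(cm_values(m), na.rm = TRUE))
    expect_lte(max(v, na.rm = TRUE), max(cm_values(m), na.rm = TRUE))
  }
  # all-missing input stays missing, never becomes zero
  ma <- random_cm(4, 4, seed = 5)
  ma$values[] <- NA_real_
  expect_true(all(is.na(cm_values(smooth_matrix(ma, 1e6)))))
})

test_that("differential subtraction is antisymmetric and strict about inputs", {
  a <- random_cm(6, 6, seed = 21)
  b <- a
  b$values[] <- withr::with_seed(22, stats::runif(36, 0, 10))
  d1 <- differential_matrix(a, b)
  d2 <- differential_matrix(b, a)
  expect_equal(cm_values(d1), -cm_values(d2))
  expect_true(all(cm_values(differential_matrix(a, a)) == 0))
  # missing in either input propagates
  b$values[1, 1] <- NA
  expect_true(is.na(cm_values(differential_matrix(a, b))[1, 1]))
  # state and axis mismatches are errors
  raw <- random_cm(6, 6, seed = 23, state = "raw")
  expect_error(differential_matrix(a, raw), "same state")
  expect_error(differential_matrix(raw, raw), "raw counts")
  shifted <- random_cm(6, 6, seed = 24)
  expect_error(differential_matrix(a, shifted), "axes")
})

test_that("replicate agreement is 1 for identity and ~0 for permuted cells", {
  a <- random_cm(10, 10, seed = 31)
  expect_equal(replicate_agreement(a, a), 1.0)
  b <- a
  b$values[] <- withr::with_seed(32, sample(a$values))
  expect_lt(abs(replicate_agreement(a, b)), 0.1)
  tiny <- random_cm(2, 1, seed = 33)
  expect_error(replicate_agreement(tiny, tiny), "3 shared")
})

test_that("two multinomial resamples of one expected matrix agree strongly", {
  p <- contact_model_params(region_length = 120e3, site_density = 0.25,
                            tad_boundaries = 60e3, seed = 40)
  reg <- simulate_region(p)
  em <- expected_matrix(reg$fragments, reg$params)
  r1 <- normalize_matrix(simulate_counts(em, 1e5, seed = 41), 1e5)
  r2 <- normalize_matrix(simulate_counts(em, 1e5, seed = 42), 1e5)
  expect_gt(replicate_agreement(r1, r2), 0.9)
})

test_that("matrix TSV round-trips losslessly with axis metadata", {
  m <- random_cm(5, 4, seed = 51, p_na = 0.2)
  m$genome <- "mm9"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(m, path)
  back <- read_contact_matrix(path)
  expect_equal(cm_values(back), cm_values(m), tolerance = 1e-7)
  expect_equal(GenomicRanges::start(back$row_ranges),
               GenomicRanges::start(m$row_ranges))
  expect_equal(GenomicRanges::end(back$col_ranges),
               GenomicRanges::end(m$col_ranges))
  expect_equal(back$genome, "mm9")
  expect_equal(rownames(cm_values(back)), rownames(cm_values(m)))
})
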