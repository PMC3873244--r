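A_KEY <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"
P1_KEY <- "ATCACCGACTGCCCATAGAGAGG"

test_that("alternating design alternates F,R from the first fragment", {
  d <- tiny_design(rep(60, 6), "alternating")$design
  expect_equal(d$primers$orientation,
               rep(c("forward", "reverse"), 3))
  # single fragment: one forward primer
  d1 <- tiny_design(60, "alternating")$design
  expect_equal(d1$primers$orientation, "forward")
  # |#F - #R| <= 1 over random fragment counts
  for (n in c(2, 5, 9)) {
    dn <- tiny_design(rep(60, n), "alternating", seed = n)$design
    tab <- table(dn$primers$orientation)
    expect_lte(abs(tab[["forward"]] - sum(dn$primers$orientation == "reverse")), 1)
  }
})

test_that("primer tails and phosphorylation follow orientation", {
  d <- tiny_design(rep(60, 6), "alternating")$design
  fwd <- d$primers[d$primers$orientation == "forward", ]
  rev <- d$primers[d$primers$orientation == "reverse", ]
  expect_true(all(startsWith(fwd$full_sequence, A_KEY)))
  expect_true(all(endsWith(rev$full_sequence, P1_KEY)))
  expect_true(all(rev$phosphorylated_5prime))
  expect_false(any(fwd$phosphorylated_5prime))
  expect_equal(fwd$full_sequence, paste0(A_KEY, fwd$core_sequence))
  expect_equal(rev$full_sequence, paste0(rev$core_sequence, P1_KEY))
})

test_that("primer cores sit at the cut-adjacent fragment ends", {
  fx <- tiny_design(rep(60, 4), "alternating")
  d <- fx$design
  frags <- fx$fragments
  for (i in seq_len(nrow(d$primers))) {
    p <- d$primers[i, ]
    fr <- frags[S4Vectors::mcols(frags)$index == p$fragment_index]
    if (p$orientation == "forward") {
      expect_equal(p$core_sequence,
                   substring(fx$sequence, GenomicRanges::end(fr) - 29,
                             GenomicRanges::end(fr)))
    } else {
      expect_equal(p$core_sequence,
                   substring(fx$sequence, GenomicRanges::start(fr),
                             GenomicRanges::start(fr) + 29))
      # reverse cores on internal fragments start with the intact site
      expect_true(startsWith(p$core_sequence, "GAATTC"))
    }
  }
})

test_that("anchored design splits primers by the anchor region", {
  fx <- tiny_design(rep(60, 8), "anchored", anchor_frags = 5:6)
  d <- fx$design
  frags <- fx$fragments
  rev_idx <- d$primers$fragment_index[d$primers$orientation == "reverse"]
  fwd_idx <- d$primers$fragment_index[d$primers$orientation == "forward"]
  expect_equal(sort(rev_idx), 5:6)
  anchored <- IRanges::overlapsAny(frags, d$anchor_region)
  expect_true(all(!anchored[fwd_idx]))
  expect_error(design_primers(frags, fx$sequence, "anchored"),
               "anchor_region")
  far <- gr1(10^7, 10^7 + 10, "region")
  expect_error(design_primers(frags, fx$sequence, "anchored",
                              anchor_region = far), "no eligible fragment")
})

test_that("eligible fragments shorter than the primer are skipped with a warning", {
  s <- seq_with_fragment_widths(c(60, 20, 60), seed = 9)
  frags <- filter_fragments(digest(s), min_len = 1)
  expect_warning(d <- design_primers(frags, s, "alternating"), "shorter")
  expect_false(2 %in% d$primers$fragment_index)
})

test_that("junction references are the full F x R product with the site at the joint", {
  fx <- tiny_design(rep(60, 5), "alternating")
  refs <- junction_reference(fx$design)
  n_f <- sum(fx$design$primers$orientation == "forward")
  n_r <- sum(fx$design$primers$orientation == "reverse")
  expect_equal(nrow(refs), n_f * n_r)
  expect_true(all(grepl("GAATTC", refs$sequence, fixed = TRUE)))
  # reference = forward core + reverse core
  p <- fx$design$primers
  r1 <- refs[1, ]
  expect_equal(r1$sequence,
               paste0(p$core_sequence[p$primer_id == r1$forward_id],
                      p$core_sequence[p$primer_id == r1$reverse_id]))
  # a design with no reverse primers is rejected
  d1 <- tiny_design(60, "alternating")$design
  expect_error(junction_reference(d1), "forward and one reverse")
})

test_that("design tables and primer FASTA are written", {
  fx <- tiny_design(rep(60, 4), "alternating")
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_primers_fasta(fx$design, fa)
  write_design_table(fx$design, tsv)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), nrow(fx$design$primers))
  expect_equal(unname(as.character(back)), fx$design$primers$full_sequence)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$primer_id, fx$design$primers$primer_id)
})
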