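test_that("background generation hits its GC target and is seed-stable", {
  g <- generate_background(100000, gc = 0.5, seed = 9)
  obs <- sum(strsplit(g$seq, "")[[1]] %in% c("G", "C")) / 100000
  se <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(obs - 0.5), 3 * se)
  expect_identical(generate_background(5000, 0.42, seed = 4)$seq,
                   generate_background(5000, 0.42, seed = 4)$seq)
  expect_false(identical(generate_background(5000, 0.42, seed = 4)$seq,
                         generate_background(5000, 0.42, seed = 5)$seq))
  at_only <- generate_background(2000, gc = 0, seed = 1)
  expect_false(grepl("[GC]", at_only$seq))
  expect_error(generate_background(0), "positive")
})

test_that("mutation realizes its nominal divergence and reports exactly", {
  s <- strrep("ACGT", 100)
  m0 <- mutate_seq(s, 0, seed = 1)
  expect_equal(m0$seq, s)
  expect_equal(m0$realized_identity, 100)
  ids <- vapply(1:40, function(k) {
    mutate_seq(strrep("ACGT", 68), 0.05, seed = k)$realized_identity
  }, numeric(1))
  expect_equal(mean(ids), 95, tolerance = 0.01)
  # reported identity equals a position-by-position comparison
  for (k in 1:10) {
    m <- mutate_seq(s, 0.2, seed = k)
    expect_equal(m$realized_identity, naive_identity(s, m$seq))
  }
})

test_that("element assembly obeys its arithmetic and plants its features", {
  spec <- eve_spec(ltr_length = 271, ltr_divergence = 0, orf_length = 2830,
                   linker5 = 100, linker3 = 75, label = "t1")
  e <- assemble_eve(spec, seed = 6)
  expect_equal(nchar(e$seq), 2 * 271 + 100 + 75 + 3 * 2831)
  expect_equal(e$truth$realized_ltr_identity, 100)
  expect_equal(e$truth$element_length, nchar(e$seq))
  # the ORF is where truth says, translates to the planted length, and
  # carries the motif at the recorded position
  orf_nt <- substr(e$seq, e$truth$orf_start, e$truth$orf_end)
  aa <- translate_seq(orf_nt, 0)
  expect_equal(nchar(aa), 2831)                 # 2830 residues + stop
  expect_equal(substr(aa, 2831, 2831), "*")
  expect_false(grepl("\\*", substr(aa, 1, 2830)))
  expect_equal(substr(aa, e$truth$motif_pos, e$truth$motif_pos + 3), "YVDN")
})

test_that("disruptions produce what their labels promise", {
  istop <- assemble_eve(eve_spec(disruption = "internal_stop", label = "t2"),
                        seed = 6)
  aa <- translate_seq(substr(istop$seq, istop$truth$orf_start,
                             istop$truth$orf_end), 0)
  expect_true(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  solo <- assemble_eve(eve_spec(orf_length = 0, disruption = "solo_ltr",
                                label = "t3"), seed = 6)
  expect_equal(nchar(solo$seq), 271)
  expect_true(is.na(solo$truth$orf_start))
  trunc <- assemble_eve(eve_spec(disruption = "ltr_truncation",
                                 label = "t4"), seed = 6)
  expect_equal(trunc$truth$ltr3_end - trunc$truth$ltr3_start + 1L, 80L)
  expect_error(eve_spec(disruption = "solo_ltr"), "cannot carry an ORF")
  expect_error(eve_spec(ltr_length = 30), "ltr_length")
  expect_error(eve_spec(rt_motif = "ABCD"), "rt_motif")
})

test_that("planting preserves length and truth slices reproduce elements", {
  bg <- generate_background(30000, seed = 8, id = "c")
  sp1 <- eve_spec(orf_length = 450, gag_len = 135, pol_len = 135,
                  gn_len = 60, gc_len = 120, label = "p1")
  sp1$insertion_site <- 5000
  sp2 <- eve_spec(orf_length = 0, disruption = "solo_ltr", label = "p2")
  sp2$insertion_site <- 15000
  e1 <- assemble_eve(sp1, seed = 8); e1$spec <- sp1
  e2 <- assemble_eve(sp2, seed = 8); e2$spec <- sp2
  planted <- plant_eves(bg, list(e1, e2))
  expect_equal(nchar(planted$genome$seq),
               30000 + nchar(e1$seq) + nchar(e2$seq))
  # slice-and-compare: coordinates in truth reproduce each element, up to
  # the boundary-sharpened bases which live in the background
  for (i in 1:2) {
    t <- planted$truth[i, ]
    el <- list(e1, e2)[[i]]$seq
    expect_equal(substr(planted$genome$seq, t$element_start, t$element_end),
                 el)
  }
  # empty planting is the identity
  expect_identical(plant_eves(bg, list())$genome$seq, bg$seq)
  # overlapping sites are refused
  e3 <- e1; e3$spec$insertion_site <- 5000
  expect_error(plant_eves(bg, list(e1, e3)), "overlapping")
})

test_that("degenerate envelope cassette lengths are rejected", {
  expect_error(eve_spec(orf_length = 400, gag_len = 130, pol_len = 135,
                        gn_len = 0, gc_len = 135), "too short")
  expect_error(eve_spec(orf_length = 400, gag_len = 100, pol_len = 100,
                        gn_len = 100, gc_len = 150), "sum to orf_length")
})
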