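test_that("an identical planted repeat pair is recovered exactly", {
  set.seed(21)
  ltr <- paste0("TG", random_dna_str(267), "CA")
  interior <- random_dna_str(2000)
  locus <- make_test_locus(ltr, interior, random_dna_str(900),
                           random_dna_str(900))
  p <- find_ltr_pair(locus, flank_window = 1500)
  expect_equal(p$classification, "intact")
  expect_equal(p$length, 271L)
  expect_equal(p$identity_pct, 100)
  expect_equal(c(p$ltr5_start, p$ltr5_end), c(901, 1171))
  expect_equal(c(p$ltr3_start, p$ltr3_end), c(3172, 3442))
  el <- delimit_element(p)
  expect_equal(el$element_length, 2 * 271 + 2000)
})

test_that("substitutions in the repeat interior lower identity by count", {
  set.seed(22)
  ltr <- paste0("TG", random_dna_str(267), "CA")
  # mutate 5 interior sites, away from the termini
  ch <- strsplit(ltr, "")[[1]]
  pos <- sample(30:240, 5)
  for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  ltr3 <- paste0(ch, collapse = "")
  locus <- make_test_locus(ltr, random_dna_str(2000), random_dna_str(900),
                           random_dna_str(900), ltr3 = ltr3)
  p <- find_ltr_pair(locus, flank_window = 1500)
  expect_equal(p$length, 271L)
  expect_equal(p$identity_pct, 100 * 266 / 271)
  expect_equal(p$classification, "intact")     # 98.2% >= 95
  # and find_ltr_pair's identity equals identity_matrix on the extracted pair
  r5 <- substr(locus, p$ltr5_start, p$ltr5_end)
  r3 <- substr(locus, p$ltr3_start, p$ltr3_end)
  im <- identity_matrix(c(a = r5, b = r3))
  expect_equal(p$identity_pct, im["a", "b"])
})

test_that("repeat detection is invariant under reverse complement", {
  set.seed(23)
  ltr <- paste0("TG", random_dna_str(267), "CA")
  locus <- make_test_locus(ltr, random_dna_str(2000), random_dna_str(900),
                           random_dna_str(900))
  p <- find_ltr_pair(locus, flank_window = 1500)
  q <- find_ltr_pair(revcomp(locus), flank_window = 1500)
  expect_equal(q$length, p$length)
  expect_equal(q$identity_pct, p$identity_pct)
  expect_equal(q$score, p$score)
  L <- nchar(locus)
  expect_equal(q$ltr5_start, L - p$ltr3_end + 1)
  expect_equal(q$ltr3_end, L - p$ltr5_start + 1)
})

test_that("identity_matrix is symmetric with unit diagonal and exact counts", {
  set.seed(24)
  base <- random_dna_str(200)
  for (i in 1:20) {
    k <- sample(0:30, 1)
    other <- substitute_k(base, k)
    im <- identity_matrix(c(x = base, y = other))
    expect_equal(im["x", "y"], 100 * (200 - k) / 200)
    expect_equal(im["x", "y"], im["y", "x"])
    expect_equal(diag(im), c(x = 100, y = 100))
  }
  expect_error(identity_matrix(character(0)), "at least 2")
  im2 <- identity_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(im2["a", "b"], 100)
})

test_that("truncated and solo repeats are classified from context", {
  set.seed(25)
  ltr <- paste0("TG", random_dna_str(267), "CA")
  interior <- random_dna_str(2000)
  # 3' copy clipped to 80 nt at the very end of the contig
  locus <- paste0(random_dna_str(900), ltr, interior, substr(ltr, 1, 80))
  p <- find_ltr_pair(locus, flank_window = 1500, at_contig_end = TRUE)
  expect_equal(p$classification, "truncated")
  expect_equal(p$length, 80L)
  expect_error(delimit_element(p), "intact or degenerate")
  # same call without the contig-end context: no classification
  p2 <- find_ltr_pair(paste0(random_dna_str(900), ltr, interior,
                             substr(ltr, 1, 80), random_dna_str(900)),
                      flank_window = 1500)
  expect_equal(p2$classification, "none")
  # a single copy with a known reference is a solo
  solo_locus <- paste0(random_dna_str(700), ltr, random_dna_str(700))
  expect_equal(
    classify_ltr(NULL, locus_length = nchar(solo_locus),
                 locus_seq = solo_locus, reference_ltr = ltr),
    "solo")
})

test_that("detected identity tracks the divergence grid monotonically", {
  divs <- c(0, 0.05, 0.1, 0.15, 0.2)
  means <- vapply(divs, function(d) {
    vals <- vapply(1:8, function(s) {
      ltr <- evescreen:::with_seed(
        evescreen:::substream_seed(s, sprintf("g-%g", d)),
        evescreen:::random_dna(271, 0.42))
      mutate_seq(ltr, d, seed = s * 1000 + round(d * 100))$realized_identity
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_equal(means, 100 * (1 - divs), tolerance = 0.02)
})

test_that("loci shorter than twice the minimum repeat are refused", {
  expect_error(find_ltr_pair(random_dna_str(150), min_len = 100),
               "shorter than twice")
})
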