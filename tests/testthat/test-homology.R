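test_that("self-alignment scores the diagonal sum and symmetry holds", {
  a <- "MKVLATWYCD"
  r <- smith_waterman(a, a)
  expect_equal(r$score,
               sum(diag(blosum62()[strsplit(a, "")[[1]],
                                   strsplit(a, "")[[1]]])))
  expect_equal(r$identity_pct, 100)
  set.seed(11)
  for (i in 1:25) {
    x <- random_protein(sample(3:9, 1)); y <- random_protein(sample(3:9, 1))
    expect_equal(smith_waterman(x, y)$score, smith_waterman(y, x)$score)
    # invariant under simultaneous reversal of both sequences
    rx <- paste(rev(strsplit(x, "")[[1]]), collapse = "")
    ry <- paste(rev(strsplit(y, "")[[1]]), collapse = "")
    expect_equal(smith_waterman(x, y)$score, smith_waterman(rx, ry)$score)
  }
})

test_that("empty input gives score 0 with an empty alignment", {
  r <- smith_waterman("", "MKV")
  expect_equal(r$score, 0)
  expect_equal(r$aligned_length, 0L)
  expect_equal(r$a_start, 0L)
})

test_that("local and global scores agree with an independently written DP", {
  set.seed(12)
  S <- blosum62()
  for (i in 1:60) {
    x <- random_protein(sample(1:8, 1)); y <- random_protein(sample(1:8, 1))
    go <- sample(c(5, 11), 1); ge <- sample(c(1, 2), 1)
    expect_equal(
      global_align(x, y, gap_open = go, gap_extend = ge)$score,
      oracle_global_score(strsplit(x, "")[[1]], strsplit(y, "")[[1]], S, go, ge))
  }
})

test_that("the exhaustive alignment enumeration agrees with the DP oracle", {
  set.seed(13)
  S <- blosum62()
  for (i in 1:40) {
    x <- strsplit(random_protein(sample(1:4, 1)), "")[[1]]
    y <- strsplit(random_protein(sample(1:4, 1)), "")[[1]]
    expect_equal(oracle_global_score(x, y, S, 11, 1),
                 oracle_enumerate_global(x, y, S, 11, 1))
  }
})

test_that("a preferred gap placement is found (one gap opposite the extra D)", {
  g <- global_align("ACDEFG", "ACEFG")
  expect_equal(g$a_aln, "ACDEFG")
  expect_equal(g$b_aln, "AC-EFG")
})

test_that("bit scores implement the Karlin-Altschul map", {
  expect_equal(bit_score(0, 0.267, 0.041), -log(0.041) / log(2),
               tolerance = 1e-12)
  expect_equal(round(bit_score(0), 2), 4.61)
  raw <- seq(0, 500, by = 25)
  expect_true(all(diff(bit_score(raw)) > 0))
  raw0 <- log(0.041) / 0.267
  expect_equal(bit_score(raw0), 0, tolerance = 1e-12)
  expect_error(bit_score(10, lambda = -1), "lambda")
})

test_that("PSSM construction has the documented limits and symmetries", {
  S <- blosum62()
  res <- names(evescreen:::blosum62_background())
  # single row, huge pseudocount: scores approach the closed-form limit
  # 2*log2(g/bg) with g the matrix-implied conditional distribution
  p <- build_pssm("K", pseudocount = 1e7)
  bg <- evescreen:::blosum62_background()
  g <- bg * 2^(S["K", res] / 2); g <- g / sum(g)
  expect_equal(p$scores[1, ], 2 * log2(g / bg), tolerance = 1e-4,
               ignore_attr = TRUE)
  # and those limits track the substitution scores themselves
  expect_lt(max(abs(p$scores[1, ] - S["K", res])), 0.75)
  # pure column, small pseudocount: the observed residue scores highest
  p2 <- build_pssm(c("K", "K", "K"), pseudocount = 0.01)
  expect_gt(p2$scores[1, "K"], 0)
  expect_equal(names(which.max(p2$scores[1, ])), "K")
  # row order irrelevant
  rows <- c("KAC", "KDE", "RGH")
  expect_equal(build_pssm(rows)$scores, build_pssm(rev(rows))$scores)
  # ragged alignments refused; mostly-gap columns dropped
  expect_error(build_pssm(c("AB", "A")), "ragged")
  p3 <- build_pssm(c("A-C", "A-C", "AGC"))
  expect_equal(nrow(p3$scores), 2L)
  expect_equal(p3$positions, c(1L, 3L))
})

test_that("PSSM round-trips through its TSV serialization", {
  p <- build_pssm(c("KAC", "KDE", "RGH"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pssm(p, f)
  q <- read_pssm(f)
  expect_equal(unname(q$scores), unname(p$scores), tolerance = 1e-12)
  expect_equal(q$positions, p$positions)
})

test_that("genome scanning finds a planted cassette in any orientation", {
  set.seed(14)
  cassette <- random_protein(120)
  nt <- evescreen:::with_seed(99, evescreen:::reverse_translate(cassette))
  genome <- tibble::tibble(
    id = "c1",
    seq = paste0(random_dna_str(3000), nt, random_dna_str(3000)))
  query <- tibble::tibble(id = "q", seq = cassette)
  hits <- scan_genome(genome, query)
  expect_gte(nrow(hits), 1)
  top <- hits[1, ]
  expect_equal(top$identity_pct, 100)
  expect_equal(c(top$t_start, top$t_end), c(3001, 3000 + nchar(nt)))
  expect_gt(top$frame, 0)
  # reverse complement: same score on a negative frame, mirrored span
  hits_rc <- scan_genome(tibble::tibble(id = "c1", seq = revcomp(genome$seq)),
                         query)
  expect_equal(hits_rc$raw[1], top$raw)
  expect_lt(hits_rc$frame[1], 0)
  L <- nchar(genome$seq)
  expect_equal(c(hits_rc$t_start[1], hits_rc$t_end[1]),
               c(L - top$t_end + 1, L - top$t_start + 1))
})

test_that("a shuffled decoy query finds nothing in clean background", {
  for (s in 1:3) {
    g <- generate_background(100000, gc = 0.42, seed = s, id = "bg")
    q <- evescreen:::with_seed(s, random_protein(150))
    hits <- scan_genome(g, tibble::tibble(id = "decoy", seq = q))
    expect_equal(nrow(hits), 0)
  }
})

test_that("hit merging bridges gaps up to the window and sorts loci", {
  hits <- tibble::tibble(
    query = c("q1", "q2", "q1"), contig = "c1", frame = c(2L, 2L, 2L),
    t_start = c(100L, 1500L, 9000L), t_end = c(900L, 2400L, 9600L),
    q_start = 1L, q_end = 100L, raw = c(500, 400, 300),
    bits = c(190, 152, 114), identity_pct = 90, aligned_length = 100L,
    q_aln = "A", t_aln = "A")
  loci <- merge_hits(hits, merge_gap = 1000)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$start, c(100L, 9000L))
  expect_equal(loci$end, c(2400L, 9600L))
  expect_equal(loci$n_hits, c(2L, 1L))
})
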