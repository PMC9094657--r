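# naive ATG-to-stop enumeration across both strands
naive_longest_orf <- function(seq, min_codons = 100) {
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    for (off in 0:2) {
      aa <- translate_seq(s, off)
      codons <- strsplit(aa, "")[[1]]
      i <- 1
      while (i <= length(codons)) {
        if (codons[i] == "M") {
          j <- i
          while (j <= length(codons) && codons[j] != "*") j <- j + 1
          if (j <= length(codons)) {
            len <- j - i
            if (len >= min_codons && (is.null(best) || len > best$len)) {
              best <- list(len = len, strand = strand)
            }
            i <- j + 1
            next
          } else break
        }
        i <- i + 1
      }
    }
  }
  best
}

test_that("longest ORF agrees with exhaustive enumeration", {
  set.seed(31)
  for (i in 1:15) {
    s <- random_dna_str(sample(500:3000, 1))
    mine <- longest_orf(s, min_codons = 10)
    ref <- naive_longest_orf(s, min_codons = 10)
    if (is.null(ref)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(mine$length_aa, ref$len)
    }
  }
})

test_that("a planted uninterrupted ORF is recovered at full length", {
  set.seed(32)
  prot <- random_protein(400)
  prot <- paste0("M", substr(prot, 2, 400))
  nt <- evescreen:::with_seed(1, evescreen:::reverse_translate(prot))
  interior <- paste0("TAAATAAATAAA", nt, "TAA", "TAAATAAATAAA")
  orf <- longest_orf(interior)
  expect_equal(orf$length_aa, 400L)
  expect_equal(orf$internal_stops, 0L)
  expect_true(orf$has_start)
  expect_equal(orf$protein, prot)
  expect_equal(check_integrity(orf, interior_length = nchar(interior),
                               min_codons = 300), "complete")
  # a mid-ORF stop breaks integrity
  nt2 <- paste0(substr(nt, 1, 597), "TAA", substr(nt, 601, nchar(nt)))
  orf2 <- longest_orf(paste0("TAAATAAATAAA", nt2, "TAATAAATAAATAAA"))
  expect_lt(orf2$length_aa, 400L)
  expect_equal(check_integrity(orf2, interior_length = nchar(interior),
                               min_codons = 300), "interrupted")
})

test_that("integrity verdicts cover absent and coverage failure", {
  expect_equal(check_integrity(longest_orf("ACGTACGTACGT")), "absent")
  orf <- longest_orf(paste0("ATG", strrep("GCA", 200), "TAA"), min_codons = 50)
  expect_equal(check_integrity(orf, interior_length = NA, min_codons = 100),
               "complete")
  # same ORF inside a much larger interior fails the coverage rule
  expect_equal(check_integrity(orf, interior_length = 10000,
                               min_codons = 100), "interrupted")
})

test_that("polymerase motif scan matches the naive oracle and classifies", {
  hit <- scan_polymerase_motif(paste0(strrep("A", 100), "GYVDNQ",
                                      strrep("A", 100)),
                               span = c(1, 206))
  expect_equal(hit$motif, "YVDN")
  expect_equal(hit$variant_class, "variant_YXDN")
  hit2 <- scan_polymerase_motif(paste0(strrep("A", 50), "AYMDDV",
                                       strrep("A", 50)), span = c(1, 106))
  expect_equal(hit2$motif, "YMDD")
  expect_equal(hit2$variant_class, "canonical_YXDD")
  expect_equal(scan_polymerase_motif(strrep("A", 120))$variant_class, "none")
  set.seed(33)
  for (i in 1:200) {
    p <- random_protein(sample(30:120, 1))
    span <- c(floor(nchar(p) / 3) + 1, min(nchar(p), 2 * ceiling(nchar(p) / 3)))
    mine <- scan_polymerase_motif(p)
    ref <- naive_motif(p, span[1], span[2])
    # the naive scan may run past the span end; clamp like the implementation
    if (!is.na(ref) && ref > span[2] - 3) ref <- NA_integer_
    if (is.na(ref)) {
      expect_equal(mine$variant_class, "none")
    } else {
      expect_equal(mine$position, ref)
    }
  }
})

test_that("motif search defaults to the middle third", {
  # motif in the first third is invisible by default, found with full span
  p <- paste0("AAYVDNAA", strrep("G", 292))
  expect_equal(scan_polymerase_motif(p)$variant_class, "none")
  expect_equal(scan_polymerase_motif(p, span = c(1, nchar(p)))$position, 3L)
})

test_that("polyprotein partition anchors on motif and env hits", {
  part <- partition_polyprotein(
    2830,
    env_hits = tibble::tibble(start = 1890L, end = 2828L, bits = 500),
    motif = tibble::tibble(motif = "YVDN", position = 1415L,
                           variant_class = "variant_YXDN"),
    rt_upstream = 470)
  expect_equal(part$start[part$region == "env"], 1890L)
  expect_equal(part$end[part$region == "pol"], 1889L)
  expect_equal(part$start[part$region == "pol"], 1415L - 470L)
  expect_equal(part$end[part$region == "gag"], 1415L - 471L)
  # no env evidence: env undetermined, gag/pol still anchored
  part2 <- partition_polyprotein(
    2830, env_hits = NULL,
    motif = tibble::tibble(motif = "YVDN", position = 1415L,
                           variant_class = "variant_YXDN"))
  expect_true(is.na(part2$start[part2$region == "env"]))
  expect_false(is.na(part2$start[part2$region == "pol"]))
})
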