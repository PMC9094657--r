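test_that("FASTA reading parses records, normalizes case and keeps order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b desc ignored", "acgt", "NNAA"), f)
  x <- read_fasta(f)
  expect_equal(x$id, c("a", "b"))
  expect_equal(x$seq, c("ACGT", "ACGTNNAA"))
  expect_equal(x$length, c(4L, 8L))
  expect_equal(attr(x, "type"), "dna")
})

test_that("FASTA parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "", ">b", "ACGT"), f)
  expect_error(read_fasta(f), "line 1.*empty sequence")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">a", "ACRT"), f)       # R is an ambiguity code, rejected
  expect_error(read_fasta(f, type = "dna"), "illegal character 'R'")
})

test_that("write_fasta/read_fasta round-trips byte-identically at fixed width", {
  set.seed(1)
  seqs <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    seq = vapply(c(10, 60, 135), random_dna_str, character(1))
  )
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f1, width = 60)
  back <- read_fasta(f1)
  expect_equal(back$seq, seqs$seq)
  write_fasta(back, f2, width = 60)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("revcomp satisfies its defining cases and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAAC"), "GTTT")
  expect_equal(revcomp("ANT"), "ANT")
  expect_error(revcomp("ACGU"), "illegal")
  set.seed(2)
  for (i in 1:20) {
    s <- random_dna_str(sample(1:50, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("translation follows the standard code, frames and N handling", {
  expect_equal(translate_seq("ATGTAA", 0), "M*")
  expect_equal(translate_seq("ATGGCC", 1), "W")   # TGG, trailing CC dropped
  expect_equal(translate_seq("ATGNNNTAA", 0), "MX*")
  set.seed(3)
  s <- random_dna_str(99)
  fr <- six_frame(s)
  # every codon of the forward strand appears in exactly one forward frame
  expect_equal(sum(nchar(fr$aa[fr$frame > 0])), sum((99 - 0:2) %/% 3))
  # reverse frames translate the reverse complement
  expect_equal(fr$aa[fr$frame == -1], translate_seq(revcomp(s), 0))
})

test_that("GFF3 output round-trips through rtracklayer and checks bounds", {
  feats <- tibble::tibble(
    seqid = "chr1", start = c(10L, 100L), end = c(50L, 400L),
    strand = c("+", "+"), type = c("LTR", "element"),
    attributes = list(list(label = "x"), list(label = "y"))
  )
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, f, contig_lengths = c(chr1 = 1000))
  expect_match(readLines(f, n = 1), "gff-version 3")
  back <- read_gff3(f)
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
  expect_equal(back$type, feats$type)
  expect_error(write_gff3(feats, f, contig_lengths = c(chr1 = 300)),
               "out of contig bounds")
  expect_error(
    write_gff3(dplyr::mutate(feats, type = "bogus"), f),
    "unknown feature type")
})

test_that("report table has the documented schema, even when empty", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report_table(NULL, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(hdr, c("locus_id", "element_length_bp", "ltr_length_bp",
                      "ltr_identity_pct", "polyprotein_length_aa",
                      "rt_motif", "env_class", "verdict"))
  expect_equal(length(readLines(f)), 1L)
})
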