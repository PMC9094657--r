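# Small deterministic fixtures built in code.

# A locus with a planted terminal-repeat pair and sharp repeat boundaries
# (the bases adjacent to each repeat copy are forced to mismatch their
# alignment-extension counterparts, so the planted pair is the unique
# maximal local alignment).
make_test_locus <- function(ltr, interior, flank_l, flank_r, ltr3 = ltr) {
  fix <- function(s, i, forbidden) {
    if (substr(s, i, i) == forbidden) {
      substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), forbidden)[1]
    }
    s
  }
  nl <- nchar(flank_l); ni <- nchar(interior)
  for (k in 0:5) {
    # before 5' copy vs before 3' copy (interior tail)
    flank_l <- fix(flank_l, nl - k, substr(interior, ni - k, ni - k))
    # after 5' copy (interior head) vs after 3' copy (right flank)
    flank_r <- fix(flank_r, k + 1, substr(interior, k + 1, k + 1))
  }
  paste0(flank_l, ltr, interior, ltr3, flank_r)
}
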