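# Scoring machinery shared by the homology search, the LTR finder and the
# progressive aligner. The DP engine lives in src/align.cpp; everything here
# is encoding, matrix construction and result tidying.

aln_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The 25-letter BLOSUM62 matrix (20 residues plus B, J, Z, X and `*`)
#' shipped with Biostrings, the community default for protein local
#' alignment.
#'
#' @return Integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(aln_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aln_env$blosum62 <- e$BLOSUM62
  }
  aln_env$blosum62
}

# BLOSUM62 background (Robinson-Robinson style marginals of the BLOSUM62
# target frequencies); used as the null model for PSSM log-odds.
blosum62_background <- function() {
  c(A = 0.0742, R = 0.0516, N = 0.0446, D = 0.0536, C = 0.0246,
    Q = 0.0343, E = 0.0543, G = 0.0741, H = 0.0262, I = 0.0679,
    L = 0.0989, K = 0.0582, M = 0.0250, F = 0.0474, P = 0.0385,
    S = 0.0572, T = 0.0508, W = 0.0131, Y = 0.0321, V = 0.0729)
}

#' Nucleotide match/mismatch scoring matrix
#'
#' @param match Match score (default +2).
#' @param mismatch Mismatch score (default -3).
#' @return 5x5 matrix over A, C, G, T, N; N scores 0 against everything.
#' @export
nt_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

encode_seq <- function(seq, alphabet) {
  if (!nzchar(seq)) return(integer(0))
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, alphabet)
  if (anyNA(codes)) {
    abort(paste0("character '", chars[which(is.na(codes))[1]],
                 "' not in scoring alphabet"))
  }
  codes
}

aln_strings <- function(a, b, a_idx, b_idx) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  list(
    a = paste0(ifelse(a_idx > 0, ac[pmax(a_idx, 1)], "-"), collapse = ""),
    b = paste0(ifelse(b_idx > 0, bc[pmax(b_idx, 1)], "-"), collapse = "")
  )
}

aln_identity <- function(a, b, a_idx, b_idx) {
  if (!length(a_idx)) return(list(matches = 0L, columns = 0L, pct = NA_real_))
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  both <- a_idx > 0 & b_idx > 0
  matches <- sum(both & ac[pmax(a_idx, 1)] == bc[pmax(b_idx, 1)])
  list(matches = as.integer(matches), columns = length(a_idx),
       pct = 100 * matches / length(a_idx))
}

tidy_alignment <- function(raw, a, b) {
  strs <- aln_strings(a, b, raw$a_idx, raw$b_idx)
  idn <- aln_identity(a, b, raw$a_idx, raw$b_idx)
  tibble(
    score = raw$score,
    a_start = raw$a_start, a_end = raw$a_end,
    b_start = raw$b_start, b_end = raw$b_end,
    aligned_length = length(raw$a_idx),
    matches = idn$matches,
    identity_pct = idn$pct,
    a_aln = strs$a, b_aln = strs$b
  )
}

#' Optimal local alignment (Smith-Waterman) with affine gaps
#'
#' Exact (non-heuristic) local alignment. A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`. When no positive-scoring path exists
#' (including empty input) the score is 0 with an empty alignment.
#'
#' @param a,b Sequences (single strings) over the alphabet of `matrix`.
#' @param matrix Substitution matrix with dimnames (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap costs, `gap_open >= gap_extend`.
#' @return One-row tibble: `score`, `a_start`/`a_end`/`b_start`/`b_end`
#'   (1-based inclusive, 0 when empty), `aligned_length`, `matches`,
#'   `identity_pct` (percent over aligned columns), `a_aln`, `b_aln`.
#' @export
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 11,
                           gap_extend = 1) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  alpha <- rownames(matrix)
  av <- encode_seq(toupper(a), alpha)
  bv <- encode_seq(toupper(b), alpha)
  raw <- c_local_align(av, bv, matrix, gap_open, gap_extend,
                       max(length(av), 1L), max(length(bv), 1L))
  tidy_alignment(raw, toupper(a), toupper(b))
}

#' Optimal global alignment (Needleman-Wunsch) with affine gaps
#'
#' @inheritParams smith_waterman
#' @return One-row tibble as for [smith_waterman()]; `identity_pct` is
#'   computed over all aligned columns including gap columns.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                         gap_extend = 1) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  alpha <- rownames(matrix)
  av <- encode_seq(toupper(a), alpha)
  bv <- encode_seq(toupper(b), alpha)
  raw <- c_global_align(av, bv, matrix, gap_open, gap_extend)
  tidy_alignment(raw, toupper(a), toupper(b))
}
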