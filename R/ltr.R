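# Terminal-repeat detection and classification. An element of this kind is
# delimited by a pair of long terminal repeats (LTRs); both copies derive
# from one template at insertion, so their percent identity dates the
# integration (100% = recent). The finder aligns the two ends of a locus,
# the classifier turns the alignment into intact / degenerate / truncated /
# solo / none, and the identity matrix reproduces repeat-set comparisons.

#' Find the terminal repeat pair of a locus
#'
#' Best-scoring local alignment between the first and last `flank_window`
#' nucleotides of the locus, subject to `min_len <= repeat length <=
#' max_len`. Repeat length is counted in alignment columns; identity is
#' percent matches over aligned columns (gap columns included).
#'
#' @param locus_seq Locus nucleotide sequence (element plus flanks).
#' @param flank_window Window searched at each end (default 1500 nt; capped
#'   at half the locus length).
#' @param min_len,max_len Accepted repeat length range (defaults 100/1500).
#' @param match,mismatch,gap_open,gap_extend Alignment scores (+2/-3, gaps
#'   5/2 as positive costs).
#' @param min_score Minimum alignment score for any repeat call (default 60).
#' @param intact_threshold Identity (percent) at or above which a
#'   full-length pair is intact (default 95).
#' @param truncated_min_len Minimum aligned length for a truncated call
#'   (default 40).
#' @param end_margin A short repeat copy within this many nt of a contig
#'   end supports a truncated call (default 25).
#' @param at_contig_start,at_contig_end Whether the locus abuts the contig
#'   start/end (known to the caller that extracted the locus).
#' @return One-row tibble (`ltr5_start`, `ltr5_end`, `ltr3_start`,
#'   `ltr3_end` in locus coordinates, `length`, `identity_pct`, `score`,
#'   `classification`). Coordinates are 0 for classification `"none"`.
#' @export
find_ltr_pair <- function(locus_seq, flank_window = 1500, min_len = 100,
                          max_len = 1500, match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2, min_score = 60,
                          intact_threshold = 95, truncated_min_len = 40,
                          end_margin = 25,
                          at_contig_start = FALSE, at_contig_end = FALSE) {
  len <- nchar(locus_seq)
  if (len <= 2 * min_len) abort("locus shorter than twice min_len")
  stopifnot(min_len <= max_len)
  fw <- min(flank_window, floor(len / 2))
  if (max_len > fw) max_len <- fw
  head_seq <- substr(locus_seq, 1, fw)
  tail_off <- len - fw            # tail position j maps to locus tail_off + j
  tail_seq <- substr(locus_seq, tail_off + 1, len)
  S <- nt_matrix(match, mismatch)
  aln <- smith_waterman(head_seq, tail_seq, matrix = S,
                        gap_open = gap_open, gap_extend = gap_extend)
  none <- tibble(ltr5_start = 0L, ltr5_end = 0L, ltr3_start = 0L,
                 ltr3_end = 0L, length = 0L, identity_pct = NA_real_,
                 score = aln$score, classification = "none")
  if (aln$score < min_score || aln$aligned_length < truncated_min_len) {
    return(none)
  }
  aln <- trim_repeat_alignment(aln, floor = truncated_min_len)
  if (aln$aligned_length < truncated_min_len) return(none)
  # polish: exact ungapped extension of the trimmed core to the true
  # repeat boundary (extends only while both next characters are equal)
  hc <- strsplit(head_seq, "")[[1]]
  tc <- strsplit(tail_seq, "")[[1]]
  while (aln$a_start > 1 && aln$b_start > 1 &&
         hc[aln$a_start - 1] == tc[aln$b_start - 1]) {
    aln$a_start <- aln$a_start - 1L
    aln$b_start <- aln$b_start - 1L
    ch <- hc[aln$a_start]
    aln$a_aln <- paste0(ch, aln$a_aln); aln$b_aln <- paste0(ch, aln$b_aln)
    aln$aligned_length <- aln$aligned_length + 1L
    aln$matches <- aln$matches + 1L
  }
  while (aln$a_end < fw && aln$b_end < fw &&
         hc[aln$a_end + 1] == tc[aln$b_end + 1]) {
    aln$a_end <- aln$a_end + 1L
    aln$b_end <- aln$b_end + 1L
    ch <- hc[aln$a_end]
    aln$a_aln <- paste0(aln$a_aln, ch); aln$b_aln <- paste0(aln$b_aln, ch)
    aln$aligned_length <- aln$aligned_length + 1L
    aln$matches <- aln$matches + 1L
  }
  aln$identity_pct <- 100 * aln$matches / aln$aligned_length
  pair <- tibble(
    ltr5_start = aln$a_start, ltr5_end = aln$a_end,
    ltr3_start = tail_off + aln$b_start, ltr3_end = tail_off + aln$b_end,
    length = aln$aligned_length,
    identity_pct = aln$identity_pct,
    score = aln$score,
    classification = NA_character_
  )
  if (pair$ltr5_end >= pair$ltr3_start) return(none)  # windows collapsed
  pair$classification <- classify_ltr(
    pair, locus_length = len, min_len = min_len, max_len = max_len,
    intact_threshold = intact_threshold,
    truncated_min_len = truncated_min_len, end_margin = end_margin,
    at_contig_start = at_contig_start, at_contig_end = at_contig_end
  )
  if (pair$classification == "none") return(none)
  pair
}

# Boundary polishing of a repeat alignment. The optimal local alignment
# can wander a few noisy (gapped, part-matching) columns past the true
# repeat boundary; since genuine repeat termini are the most constrained
# part of an LTR, terminal columns are trimmed until the outermost
# `window` columns are gap-free with at most `max_mismatch` mismatches and
# the terminal column itself is a match.
trim_repeat_alignment <- function(aln, window = 20, max_mismatch = 1,
                                  floor = 40) {
  a <- strsplit(aln$a_aln, "")[[1]]
  b <- strsplit(aln$b_aln, "")[[1]]
  n <- length(a)
  gap <- a == "-" | b == "-"
  match <- !gap & a == b
  lo <- 1; hi <- n
  repeat {
    if (hi - lo + 1 <= floor) break
    w <- lo:min(hi, lo + window - 1)
    if (!match[lo] || any(gap[w]) || sum(!match[w]) > max_mismatch) {
      lo <- lo + 1
    } else {
      break
    }
  }
  repeat {
    if (hi - lo + 1 <= floor) break
    w <- max(lo, hi - window + 1):hi
    if (!match[hi] || any(gap[w]) || sum(!match[w]) > max_mismatch) {
      hi <- hi - 1
    } else {
      break
    }
  }
  if (lo == 1 && hi == n) return(aln)
  keep <- lo:hi
  out <- aln
  out$a_start <- aln$a_start + sum(a[seq_len(lo - 1)] != "-")
  out$a_end <- aln$a_end - sum(a[seq(hi + 1, length.out = n - hi)] != "-")
  out$b_start <- aln$b_start + sum(b[seq_len(lo - 1)] != "-")
  out$b_end <- aln$b_end - sum(b[seq(hi + 1, length.out = n - hi)] != "-")
  out$aligned_length <- length(keep)
  out$matches <- sum(match[keep])
  out$identity_pct <- 100 * out$matches / out$aligned_length
  out$a_aln <- paste0(a[keep], collapse = "")
  out$b_aln <- paste0(b[keep], collapse = "")
  out
}

#' Classify a terminal-repeat call
#'
#' Rules: **intact** if the repeat is found with identity at or above
#' `intact_threshold` and length at least `min_len`; **degenerate** if found
#' at full length but identity below the threshold; **truncated** if one
#' copy is shorter than `min_len` and abuts a contig end (assembly clipped
#' it); **solo** if a `reference_ltr` is supplied and exactly one strong
#' copy of it is present with no partner; **none** otherwise.
#'
#' @param pair One-row tibble from [find_ltr_pair()] (or `NULL` when only a
#'   reference search is wanted).
#' @param locus_length Length of the locus the pair was found in.
#' @param locus_seq Locus sequence; only needed for the solo search.
#' @param reference_ltr Optional known repeat sequence for solo detection.
#' @inheritParams find_ltr_pair
#' @return Classification string.
#' @export
classify_ltr <- function(pair, locus_length = NULL, locus_seq = NULL,
                         reference_ltr = NULL, min_len = 100, max_len = 1500,
                         intact_threshold = 95, truncated_min_len = 40,
                         end_margin = 25, at_contig_start = FALSE,
                         at_contig_end = FALSE) {
  has_pair <- !is.null(pair) && nrow(pair) == 1 && pair$length > 0 &&
    !identical(pair$classification, "none")
  if (has_pair && pair$length >= min_len && pair$length <= max_len) {
    return(if (pair$identity_pct >= intact_threshold) "intact" else "degenerate")
  }
  if (has_pair && pair$length < min_len && pair$length >= truncated_min_len) {
    near_end <- (at_contig_end && !is.null(locus_length) &&
                   pair$ltr3_end >= locus_length - end_margin) ||
      (at_contig_start && pair$ltr5_start <= 1 + end_margin)
    if (near_end) return("truncated")
  }
  if (!is.null(reference_ltr) && !is.null(locus_seq)) {
    S <- nt_matrix()
    alpha <- rownames(S)
    hits <- c_local_align_multi(
      encode_seq(toupper(reference_ltr), alpha),
      encode_seq(toupper(locus_seq), alpha),
      S, 5, 2, 0.5 * 2 * nchar(reference_ltr), 8L,
      nchar(reference_ltr) + 100L, nchar(reference_ltr) + 100L)
    if (length(hits) == 1) return("solo")
  }
  "none"
}

#' Pairwise percent-identity matrix of a repeat set
#'
#' Global (end-to-end) alignment identity for every pair, percent over
#' aligned columns including internal gap columns — the conservative
#' convention of common identity matrices.
#'
#' @param repeats Character vector (optionally named) of 2 or more repeat
#'   sequences, or a tibble with `id` and `seq`.
#' @param match,mismatch,gap_open,gap_extend Alignment parameters.
#' @return Symmetric numeric matrix with 100 on the diagonal.
#' @export
identity_matrix <- function(repeats, match = 2, mismatch = -3, gap_open = 5,
                            gap_extend = 2) {
  if (is.data.frame(repeats)) repeats <- setNames(repeats$seq, repeats$id)
  if (length(repeats) < 2) abort("need at least 2 sequences")
  n <- length(repeats)
  ids <- names(repeats) %||% paste0("seq", seq_len(n))
  S <- nt_matrix(match, mismatch)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(repeats[i], repeats[j], matrix = S,
                          gap_open = gap_open, gap_extend = gap_extend)
      m[i, j] <- m[j, i] <- aln$identity_pct
    }
  }
  m
}

#' Element span delimited by an LTR pair
#'
#' From the first nucleotide of the 5' repeat to the last nucleotide of the
#' 3' repeat, inclusive. Only meaningful for intact or degenerate pairs.
#'
#' @param pair One-row tibble from [find_ltr_pair()].
#' @return One-row tibble `start`, `end`, `element_length`.
#' @export
delimit_element <- function(pair) {
  if (!pair$classification %in% c("intact", "degenerate")) {
    abort("element can only be delimited for intact or degenerate LTR pairs")
  }
  tibble(start = pair$ltr5_start, end = pair$ltr3_end,
         element_length = pair$ltr3_end - pair$ltr5_start + 1L)
}
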