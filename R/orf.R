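# Polyprotein integrity. A credible element of this family encodes its
# whole Gag-Pol-Env polyprotein as one uninterrupted reading frame; "no
# introns" is operationalized as a single ORF covering most of the
# inter-LTR interior with no internal stops (the published evidence for
# intactness is exactly that uninterrupted ORF, so no splice modeling is
# attempted). The polymerase-site motif Y-X-D-D (canonical) versus Y-X-D-N
# (the nematode belpaovirus variant) is read from the Pol third.

#' Longest open reading frame of a sequence
#'
#' ATG-to-stop ORFs across both strands and all three frames; the longest
#' wins, ties broken by strand `+` first, then leftmost start. ORFs without
#' a terminal stop codon are not counted.
#'
#' @param seq Nucleotide sequence (the element interior, or a whole locus).
#' @param min_codons Minimum length in codons for any ORF call (default
#'   100); below this the result is empty ("no ORF", not an error).
#' @return One-row tibble `start`, `end` (1-based nucleotide span on the
#'   forward strand, including the stop codon), `strand`, `frame`,
#'   `length_aa` (translated length, stop excluded), `has_start`,
#'   `internal_stops`, `protein`; zero rows if no qualifying ORF.
#' @export
longest_orf <- function(seq, min_codons = 100) {
  len <- nchar(seq)
  empty <- tibble(start = integer(), end = integer(), strand = character(),
                  frame = integer(), length_aa = integer(),
                  has_start = logical(), internal_stops = integer(),
                  protein = character())
  if (len < 3) return(empty)
  frames <- six_frame(seq)
  best <- NULL
  for (fi in seq_len(nrow(frames))) {
    aa <- frames$aa[fi]
    if (!nzchar(aa)) next
    # within each stop-delimited segment, the ORF runs from its first M
    m <- gregexpr("M[^*]*\\*", aa, perl = TRUE)[[1]]
    if (m[1] == -1) next
    ml <- attr(m, "match.length")
    for (k in seq_along(m)) {
      naa <- ml[k] - 1L           # residues translated, stop excluded
      if (naa < min_codons) next
      nt <- frame_to_nt(frames$frame[fi], m[k], m[k] + ml[k] - 1L, len)
      cand <- tibble(
        start = nt[1], end = nt[2],
        strand = if (frames$frame[fi] > 0) "+" else "-",
        frame = frames$frame[fi],
        length_aa = naa,
        has_start = TRUE,
        internal_stops = 0L,
        protein = substr(aa, m[k], m[k] + naa - 1L)
      )
      better <- is.null(best) ||
        cand$length_aa > best$length_aa ||
        (cand$length_aa == best$length_aa &&
           (cand$strand == "+" & best$strand == "-")) ||
        (cand$length_aa == best$length_aa && cand$strand == best$strand &&
           cand$start < best$start)
      if (better) best <- cand
    }
  }
  if (is.null(best)) empty else best
}

#' Polyprotein integrity verdict
#'
#' `"complete"` iff the ORF has a start codon, no internal stops, at least
#' `min_codons` residues, and covers at least `min_coverage` of the
#' inter-LTR interior (when the interior length is known). `"absent"` when
#' there is no ORF at all; `"interrupted"` otherwise.
#'
#' The `min_codons` default of 1500 reflects that the shortest credible
#' Gag-Pol-Env polyprotein is well above 1500 residues (the reference
#' element has 2828).
#'
#' @param orf Tibble from [longest_orf()] (possibly zero rows).
#' @param interior_length Inter-LTR interior length in nt, or `NA` when the
#'   element could not be delimited (the coverage test is then waived).
#' @param min_codons Minimum translated length (default 1500).
#' @param min_coverage Minimum fraction of the interior covered (default 0.8).
#' @return `"complete"`, `"interrupted"` or `"absent"`.
#' @export
check_integrity <- function(orf, interior_length = NA, min_codons = 1500,
                            min_coverage = 0.8) {
  if (is.null(orf) || nrow(orf) == 0) return("absent")
  covered <- if (is.na(interior_length)) {
    TRUE
  } else {
    (orf$end - orf$start + 1) >= min_coverage * interior_length
  }
  if (orf$has_start && orf$internal_stops == 0 &&
      orf$length_aa >= min_codons && covered) "complete" else "interrupted"
}

#' Scan for the reverse-transcriptase polymerase-site motif
#'
#' First match of Y-X-D-[D/N] in the search span. The span defaults to the
#' middle third of the polyprotein (the Pol region in the canonical
#' Gag-Pol-Env layout) to avoid chance matches in Gag or Env; pass
#' `span = c(1, nchar(polyprotein))` for a full-length scan.
#'
#' @param polyprotein Amino-acid string.
#' @param span Length-2 integer vector, 1-based inclusive residue span.
#' @return One-row tibble `motif`, `position` (1-based in the polyprotein),
#'   `variant_class` (`canonical_YXDD`, `variant_YXDN`, or `none` with NA
#'   motif/position).
#' @export
scan_polymerase_motif <- function(polyprotein, span = NULL) {
  L <- nchar(polyprotein)
  if (is.null(span)) {
    span <- c(floor(L / 3) + 1L, min(L, 2L * ceiling(L / 3)))
  }
  stopifnot(length(span) == 2, span[1] >= 1, span[2] <= L)
  region <- substr(polyprotein, span[1], span[2])
  m <- regexpr("Y[A-Z]D[DN]", region, perl = TRUE)
  if (m[1] == -1) {
    return(tibble(motif = NA_character_, position = NA_integer_,
                  variant_class = "none"))
  }
  pos <- span[1] + m[1] - 1L
  motif <- substr(polyprotein, pos, pos + 3L)
  tibble(motif = motif, position = pos,
         variant_class = if (substr(motif, 4, 4) == "D") {
           "canonical_YXDD"
         } else {
           "variant_YXDN"
         })
}

#' Partition a polyprotein into Gag, Pol and Env spans
#'
#' Env is the union of envelope-query hit spans on the polyprotein; Pol is a
#' window anchored at the polymerase motif, extended to the Env start; Gag
#' is the N-terminal remainder. `rt_upstream` sets how far the Pol span
#' reaches upstream of the motif (default 470 residues, the typical
#' protease/RT spacing in this element family). Missing anchors leave the
#' corresponding span undetermined (NA).
#'
#' @param polyprotein_length Polyprotein length in residues.
#' @param env_hits Tibble with `start`, `end` residue spans of envelope
#'   query hits on the polyprotein (may be empty/NULL).
#' @param motif Tibble from [scan_polymerase_motif()] (may be class none).
#' @param rt_upstream Residues of Pol upstream of the motif.
#' @return Tibble with rows gag/pol/env and columns `region`, `start`,
#'   `end` (NA when undetermined).
#' @export
partition_polyprotein <- function(polyprotein_length, env_hits = NULL,
                                  motif = NULL, rt_upstream = 470) {
  L <- polyprotein_length
  env <- c(NA_integer_, NA_integer_)
  if (!is.null(env_hits) && nrow(env_hits) > 0) {
    env <- c(max(1L, min(env_hits$start)), min(L, max(env_hits$end)))
  }
  has_motif <- !is.null(motif) && nrow(motif) == 1 && motif$variant_class != "none"
  pol <- c(NA_integer_, NA_integer_)
  if (has_motif) {
    pol_start <- max(1L, motif$position - as.integer(rt_upstream))
    pol_end <- if (!is.na(env[1])) env[1] - 1L else min(L, motif$position + as.integer(rt_upstream))
    if (pol_end >= pol_start) pol <- c(pol_start, pol_end)
  }
  gag <- c(NA_integer_, NA_integer_)
  if (!is.na(pol[1]) && pol[1] > 1) gag <- c(1L, pol[1] - 1L)
  tibble(region = c("gag", "pol", "env"),
         start = c(gag[1], pol[1], env[1]),
         end = c(gag[2], pol[2], env[2]))
}
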