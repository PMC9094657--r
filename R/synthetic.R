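# Synthetic genomes with planted elements and ground truth. The generator
# emulates the anatomy the screen assumes — terminal direct repeats of
# configurable length and divergence flanking a single long ORF with
# ordered Gag/Pol/Env cassettes, an RT polymerase motif, hydrophobic
# TM-like segments in Env — plus decoy loci (solo LTRs, degenerate or
# truncated LTRs, stop-codon- or frameshift-disrupted ORFs), so every
# downstream stage is testable without downloads. One user seed drives
# everything through documented substreams (see substream_seed), so whole
# benchmarks reproduce from a single integer.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

aa_weights <- c(A = 8, R = 5, N = 4, D = 5, C = 1, Q = 4, E = 6, G = 7,
                H = 2, I = 5, L = 9, K = 6, M = 2, F = 4, P = 5, S = 7,
                T = 6, W = 1, Y = 3, V = 6)

# polar alphabet for envelope regions: no asparagine (so sequons can be
# planted exactly) and no cysteine (so the census can be planted exactly)
env_alphabet <- c(A = 10, D = 8, E = 9, G = 10, H = 4, K = 9, P = 6, Q = 7,
                  R = 8, S = 10, T = 9, W = 2, Y = 5, L = 2, I = 1, V = 2,
                  F = 1, M = 1)

tm_alphabet <- c(L = 35, I = 25, V = 25, F = 10, A = 5)

# stop codons in all three frames; contains no ATG. Placed between the
# linkers and the ORF so that no reading frame runs uninterrupted across
# the planted ORF boundaries (keeps the longest ORF exactly the planted one).
stop_pad <- "TAAATAAATAAA"

random_aa <- function(n, weights = aa_weights) {
  if (n <= 0) return("")
  paste0(sample(names(weights), n, replace = TRUE,
                prob = weights / sum(weights)), collapse = "")
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(aa) {
  tab <- codon_table()
  chars <- strsplit(aa, "")[[1]]
  paste0(vapply(chars, function(r) {
    opts <- tab[[r]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

#' Generate a random background contig
#'
#' i.i.d. nucleotides with the requested GC fraction, reproducible under
#' the seed.
#'
#' @param length Contig length in nt (> 0).
#' @param gc GC fraction in (0, 1); the boundary values 0 and 1 are
#'   accepted and give AT-only / GC-only sequence.
#' @param seed Integer seed.
#' @param id Contig identifier.
#' @return Tibble `id`, `seq`, `length`.
#' @export
generate_background <- function(length, gc = 0.42, seed = 1,
                                id = "synthetic_contig") {
  if (length <= 0) abort("background length must be positive")
  if (gc < 0 || gc > 1) abort("gc must be in [0, 1]")
  seq <- with_seed(substream_seed(seed, paste0("bg-", id)),
                   random_dna(length, gc))
  tibble(id = id, seq = seq, length = nchar(seq))
}

#' Mutate a sequence by per-site substitution
#'
#' Each site substitutes with probability `divergence`, uniformly over the
#' three alternative bases. The realized identity is computed from the
#' emitted pair, not the nominal divergence.
#'
#' @param seq Nucleotide sequence.
#' @param divergence Substitution probability per site in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `seq` (mutated) and `realized_identity` (percent).
#' @export
mutate_seq <- function(seq, divergence, seed = 1) {
  stopifnot(divergence >= 0, divergence < 1)
  chars <- strsplit(seq, "")[[1]]
  out <- with_seed(substream_seed(seed, "mutate"), {
    hit <- runif(length(chars)) < divergence
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
    chars
  })
  orig <- strsplit(seq, "")[[1]]
  list(seq = paste0(out, collapse = ""),
       realized_identity = 100 * mean(out == orig))
}

#' Specification of one synthetic element
#'
#' Defaults reproduce the canonical intact element anatomy: 271-nt
#' identical LTRs around a single ORF whose translation carries ordered
#' Gag/Pol/Env cassettes, a YVDN polymerase motif mid-Pol, and two
#' 23-residue TM-like stretches in Env (one at the GN end, one C-terminal
#' in GC). `orf_length` counts translated residues; the ORF nucleotide
#' span is `3 * (orf_length + 1)` including the terminal stop codon.
#'
#' @param ltr_length LTR length in nt (>= 50).
#' @param ltr_divergence Substitutions per site applied to the 3' LTR.
#' @param orf_length Polyprotein length in residues (>= 100; must be 0 for
#'   `solo_ltr`).
#' @param rt_motif 4-residue polymerase motif matching `Y.DD` or `Y.DN`.
#' @param env_tm_count Number of TM-like stretches planted in Env (1 or 2).
#' @param disruption One of none, internal_stop, frameshift,
#'   ltr_truncation, ltr_degeneration, solo_ltr.
#' @param insertion_site 1-based position in the background at which the
#'   element is planted (`Inf` = append at the contig end).
#' @param gag_len,pol_len,gn_len,gc_len Cassette lengths in residues
#'   (defaults: thirds of `orf_length`, Env split ~47/53 into GN/GC).
#' @param linker5,linker3 Non-coding interior linkers (nt) between the
#'   LTRs and the ORF; each contains a 12-nt all-frame stop pad at the ORF
#'   boundary.
#' @param gc GC fraction used for LTR and linker sequence.
#' @param truncation_length Residual 3' LTR length for `ltr_truncation`.
#' @param label Element label used in truth records and substreams.
#' @return A list of class `eve_spec`.
#' @export
eve_spec <- function(ltr_length = 271, ltr_divergence = 0, orf_length = 2830,
                     rt_motif = "YVDN", env_tm_count = 2,
                     disruption = c("none", "internal_stop", "frameshift",
                                    "ltr_truncation", "ltr_degeneration",
                                    "solo_ltr"),
                     insertion_site = NA, gag_len = NULL, pol_len = NULL,
                     gn_len = NULL, gc_len = NULL, linker5 = 100,
                     linker3 = 75, gc = 0.42, truncation_length = 80,
                     label = "eve") {
  disruption <- match.arg(disruption)
  if (ltr_length < 50) abort("ltr_length must be >= 50")
  if (ltr_divergence < 0 || ltr_divergence >= 1) {
    abort("ltr_divergence must be in [0, 1)")
  }
  if (disruption == "solo_ltr") {
    if (orf_length != 0) abort("solo_ltr elements cannot carry an ORF")
  } else {
    if (orf_length < 100) abort("orf_length must be >= 100 codons")
    if (!grepl("^Y[A-Z]D[DN]$", rt_motif)) {
      abort("rt_motif must match Y.DD or Y.DN")
    }
  }
  if (disruption != "solo_ltr") {
    if (is.null(gag_len)) gag_len <- floor(orf_length / 3)
    if (is.null(pol_len)) pol_len <- ceiling(orf_length / 3)
    env_len <- orf_length - gag_len - pol_len
    if (is.null(gn_len)) gn_len <- round(0.47 * env_len)
    if (is.null(gc_len)) gc_len <- env_len - gn_len
    if (gag_len + pol_len + gn_len + gc_len != orf_length) {
      abort("cassette lengths must sum to orf_length")
    }
    if (gc_len < 120 || gn_len < 60) abort("env cassettes too short")
  } else {
    gag_len <- pol_len <- gn_len <- gc_len <- 0
  }
  if (disruption == "ltr_truncation" && truncation_length >= ltr_length / 2) {
    abort("truncation must clip the 3' LTR to less than half length")
  }
  structure(list(
    ltr_length = ltr_length, ltr_divergence = ltr_divergence,
    orf_length = orf_length, rt_motif = rt_motif,
    env_tm_count = env_tm_count, disruption = disruption,
    insertion_site = insertion_site, gag_len = gag_len, pol_len = pol_len,
    gn_len = gn_len, gc_len = gc_len, linker5 = linker5, linker3 = linker3,
    gc = gc, truncation_length = truncation_length, label = label
  ), class = "eve_spec")
}

# A GC-like cassette: polar backbone with a planted cysteine census
# (n_cys cysteines in positions 5..cys_max), exactly one N-X-S sequon, and
# one C-terminal TM-like 23-mer with short polar shoulders.
build_gc_region <- function(gc_len, seed, n_cys = round(30 * gc_len / 499),
                            cys_max = gc_len - 56,
                            sequon_pos = round(0.83 * gc_len),
                            tm = TRUE, tm_start = gc_len - 44) {
  with_seed(seed, {
    chars <- strsplit(random_aa(gc_len, env_alphabet), "")[[1]]
    tm_span <- integer(0)
    if (tm) {
      tm_span <- tm_start:(tm_start + 22)
      chars[tm_span] <- sample(names(tm_alphabet), 23, replace = TRUE,
                               prob = tm_alphabet / sum(tm_alphabet))
      chars[(tm_start - 4):(tm_start - 1)] <- c("S", "G", "T", "S")
      post <- (tm_start + 23):min(gc_len, tm_start + 26)
      chars[post] <- c("S", "T", "G", "S")[seq_along(post)]
    }
    if (!is.na(sequon_pos)) {
      chars[sequon_pos:(sequon_pos + 2)] <- c("N", "I", "S")
    }
    if (n_cys > 0) {
      avoid <- if (is.na(sequon_pos)) integer(0) else (sequon_pos - 2):(sequon_pos + 4)
      pool <- setdiff(5:cys_max, c(avoid, tm_span))
      pos <- pool[round(seq(1, length(pool), length.out = n_cys))]
      chars[pos] <- "C"
    }
    list(seq = paste0(chars, collapse = ""),
         tm_start = if (tm) tm_start else NA_integer_,
         sequon_pos = sequon_pos, n_cys = n_cys, cys_max = cys_max)
  })
}

# A GN-like cassette: polar backbone with (optionally) one TM-like 23-mer
# near its C terminus.
build_gn_region <- function(gn_len, seed, tm = TRUE,
                            tm_start = gn_len - 25) {
  with_seed(seed, {
    chars <- strsplit(random_aa(gn_len, env_alphabet), "")[[1]]
    if (tm) {
      chars[tm_start:(tm_start + 22)] <-
        sample(names(tm_alphabet), 23, replace = TRUE,
               prob = tm_alphabet / sum(tm_alphabet))
      chars[(tm_start - 4):(tm_start - 1)] <- c("S", "G", "T", "S")
      post <- (tm_start + 23):min(gn_len, tm_start + 26)
      chars[post] <- c("S", "T", "G", "S")[seq_along(post)]
    }
    list(seq = paste0(chars, collapse = ""),
         tm_start = if (tm) tm_start else NA_integer_)
  })
}

# Full polyprotein: Gag | Pol (motif mid-Pol) | Env (GN + GC). env_parts
# lets a caller share one envelope cassette across a family of elements.
# Draws are repeated (bounded, deterministic substreams) until the motif
# scan and the env TM count land exactly on the planted truth.
build_polyprotein <- function(spec, seed, env_parts = NULL) {
  if (is.null(env_parts)) {
    env_parts <- build_env_parts(spec, substream_seed(seed, "env"))
  }
  motif_local <- ceiling(spec$pol_len / 2)
  motif_pos <- spec$gag_len + motif_local
  env_seq <- paste0(env_parts$gn$seq, env_parts$gc$seq)
  for (try in 1:25) {
    gp <- with_seed(substream_seed(seed, paste0("gagpol-", try)), {
      gag <- random_aa(spec$gag_len)
      pol <- random_aa(spec$pol_len)
      list(gag = paste0("M", substr(gag, 2, spec$gag_len)), pol = pol)
    })
    pol_chars <- strsplit(gp$pol, "")[[1]]
    pol_chars[motif_local:(motif_local + 3)] <- strsplit(spec$rt_motif, "")[[1]]
    poly <- paste0(gp$gag, paste0(pol_chars, collapse = ""), env_seq)
    hit <- scan_polymerase_motif(poly)
    if (!is.na(hit$position) && hit$position == motif_pos &&
        hit$motif == spec$rt_motif) {
      break
    }
    if (try == 25) abort("could not plant a unique polymerase motif")
  }
  env_offset <- spec$gag_len + spec$pol_len
  tm_abs <- c(
    if (!is.na(env_parts$gn$tm_start)) env_offset + env_parts$gn$tm_start,
    if (!is.na(env_parts$gc$tm_start)) {
      env_offset + spec$gn_len + env_parts$gc$tm_start
    }
  )
  list(
    seq = poly,
    motif_pos = motif_pos,
    env_start = env_offset + 1L,
    gn_span = c(env_offset + 1L, env_offset + spec$gn_len),
    gc_span = c(env_offset + spec$gn_len + 1L, spec$orf_length),
    tm_starts = as.integer(tm_abs),
    sequon_gc = env_parts$gc$sequon_pos,
    n_cys_gc = env_parts$gc$n_cys,
    env_parts = env_parts
  )
}

build_env_parts <- function(spec, seed) {
  for (try in 1:25) {
    gn <- build_gn_region(spec$gn_len, substream_seed(seed, paste0("gn-", try)),
                          tm = spec$env_tm_count >= 2)
    gcr <- build_gc_region(spec$gc_len, substream_seed(seed, paste0("gc-", try)))
    env_seq <- paste0(gn$seq, gcr$seq)
    segs <- predict_tm_segments(hydropathy_profile(env_seq))
    sq <- scan_sequons(gcr$seq)
    ok_tm <- nrow(segs) == spec$env_tm_count
    ok_sq <- nrow(sq) == 1 && sq$position == gcr$sequon_pos
    if (ok_tm && ok_sq) return(list(gn = gn, gc = gcr))
  }
  abort("could not realize the planted envelope architecture")
}

#' Assemble one synthetic element with its ground truth
#'
#' Element layout: 5' LTR, linker, ORF (ATG ... stop), linker, 3' LTR,
#' with the 3' LTR derived from the 5' copy by [mutate_seq()] at the
#' spec's divergence. Disruptions are applied as labelled: an internal
#' stop codon or a single-nucleotide frameshift at ~45% of the ORF, 3' LTR
#' truncation, heavy LTR degeneration (divergence >= 0.15), or a solo LTR
#' with no interior at all.
#'
#' @param spec An [eve_spec()].
#' @param seed Integer seed (substreams derive from it and the label).
#' @param env_parts Optional shared envelope cassettes from a previous
#'   assembly (`truth$env_parts`), so a family of elements can carry one
#'   envelope.
#' @return List with `seq` (element nucleotide sequence), `truth` (one-row
#'   tibble of planted coordinates in element-local 1-based positions,
#'   realized LTR identity, motif, TM starts, disruption and expected
#'   screen verdict) and `env_parts`.
#' @export
assemble_eve <- function(spec, seed = 1, env_parts = NULL) {
  base <- substream_seed(seed, paste0("eve-", spec$label))
  ltr5 <- with_seed(substream_seed(base, "ltr"),
                    random_dna(spec$ltr_length, spec$gc))
  # canonical TG ... CA repeat termini
  substr(ltr5, 1, 2) <- "TG"
  substr(ltr5, spec$ltr_length - 1, spec$ltr_length) <- "CA"
  if (spec$disruption == "solo_ltr") {
    truth <- eve_truth(spec, ltr5_start = 1L, ltr5_end = spec$ltr_length,
                       ltr3_start = NA_integer_, ltr3_end = NA_integer_,
                       realized_identity = NA_real_, orf_start = NA_integer_,
                       orf_end = NA_integer_, element_length = spec$ltr_length,
                       poly = NULL)
    return(list(seq = ltr5, truth = truth, env_parts = NULL, ltr5 = ltr5))
  }
  div <- spec$ltr_divergence
  if (spec$disruption == "ltr_degeneration") div <- max(div, 0.15)
  # substitutions are planted in the repeat interior: real LTR termini are
  # the most constrained part of the repeat (TG...CA and flanking promoter
  # signals), and exact termini keep the planted boundary well defined
  protect <- 20L
  L <- spec$ltr_length
  core <- substr(ltr5, protect + 1, L - protect)
  mut <- mutate_seq(core, div, substream_seed(base, "ltr3"))
  ltr3 <- paste0(substr(ltr5, 1, protect), mut$seq,
                 substr(ltr5, L - protect + 1, L))
  realized <- 100 * (2 * protect + mut$realized_identity / 100 * nchar(core)) / L
  if (spec$disruption == "ltr_truncation") {
    ltr3 <- substr(ltr3, 1, spec$truncation_length)
    realized <- NA_real_       # identity over the full pair is undefined
  }
  poly <- build_polyprotein(spec, base, env_parts)
  orf_nt <- with_seed(substream_seed(base, "codons"), {
    paste0(reverse_translate(poly$seq), "TAA")
  })
  if (spec$disruption == "internal_stop") {
    # mid-ORF stop: both resulting fragments fall below any credible
    # complete-polyprotein length
    at <- 3 * (floor(spec$orf_length * 0.5) - 1) + 1
    orf_nt <- paste0(substr(orf_nt, 1, at - 1), "TAA",
                     substr(orf_nt, at + 3, nchar(orf_nt)))
  }
  if (spec$disruption == "frameshift") {
    at <- 3 * floor(spec$orf_length * 0.5)
    orf_nt <- paste0(substr(orf_nt, 1, at - 1),
                     substr(orf_nt, at + 1, nchar(orf_nt)))
  }
  link5 <- with_seed(substream_seed(base, "link5"), {
    paste0(random_dna(spec$linker5 - nchar(stop_pad), spec$gc), stop_pad)
  })
  link3 <- with_seed(substream_seed(base, "link3"), {
    paste0(stop_pad, random_dna(spec$linker3 - nchar(stop_pad), spec$gc))
  })
  element <- paste0(ltr5, link5, orf_nt, link3, ltr3)
  orf_start <- spec$ltr_length + spec$linker5 + 1L
  truth <- eve_truth(
    spec,
    ltr5_start = 1L, ltr5_end = spec$ltr_length,
    ltr3_start = nchar(element) - nchar(ltr3) + 1L,
    ltr3_end = nchar(element),
    realized_identity = realized,
    orf_start = orf_start, orf_end = orf_start + nchar(orf_nt) - 1L,
    element_length = nchar(element),
    poly = poly
  )
  list(seq = element, truth = truth, env_parts = poly$env_parts, ltr5 = ltr5)
}

eve_truth <- function(spec, ltr5_start, ltr5_end, ltr3_start, ltr3_end,
                      realized_identity, orf_start, orf_end, element_length,
                      poly) {
  tibble(
    label = spec$label,
    disruption = spec$disruption,
    element_length = element_length,
    ltr_length = spec$ltr_length,
    realized_ltr_identity = realized_identity,
    ltr5_start = ltr5_start, ltr5_end = ltr5_end,
    ltr3_start = ltr3_start, ltr3_end = ltr3_end,
    orf_start = orf_start, orf_end = orf_end,
    polyprotein_length = if (is.null(poly)) NA_integer_ else spec$orf_length,
    rt_motif = if (is.null(poly)) NA_character_ else spec$rt_motif,
    motif_pos = if (is.null(poly)) NA_integer_ else poly$motif_pos,
    env_start = if (is.null(poly)) NA_integer_ else poly$env_start,
    gn_start = if (is.null(poly)) NA_integer_ else poly$gn_span[1],
    gn_end = if (is.null(poly)) NA_integer_ else poly$gn_span[2],
    gc_start = if (is.null(poly)) NA_integer_ else poly$gc_span[1],
    gc_end = if (is.null(poly)) NA_integer_ else poly$gc_span[2],
    tm_starts = list(if (is.null(poly)) integer(0) else poly$tm_starts),
    gc_sequon = if (is.null(poly)) NA_integer_ else poly$sequon_gc,
    gc_cysteines = if (is.null(poly)) NA_integer_ else poly$n_cys_gc,
    expected_verdict = expected_verdict(spec$disruption, realized_identity)
  )
}

#' Expected screen verdict for a planted element
#'
#' Derived from the disruption label and the *realized* LTR identity (an
#' element planted at nominal divergence near the intact threshold is
#' expected to classify by what was actually emitted).
#'
#' @param disruption Disruption label.
#' @param realized_identity Realized LTR identity (percent; may be NA).
#' @param intact_threshold Intact identity threshold (default 95).
#' @return Verdict string.
#' @export
expected_verdict <- function(disruption, realized_identity,
                             intact_threshold = 95) {
  switch(disruption,
    none = ,
    ltr_degeneration = {
      if (!is.na(realized_identity) && realized_identity >= intact_threshold) {
        "intact_EVE_phlebovirus_env"
      } else {
        "complete_polyprotein_other_env"
      }
    },
    ltr_truncation = "complete_polyprotein_other_env",
    internal_stop = "incomplete",
    frameshift = "incomplete",
    solo_ltr = "rejected"
  )
}

#' Plant assembled elements into a background contig
#'
#' Elements are inserted at their spec insertion sites (1-based positions
#' in the original background; `Inf` appends at the contig end) and truth
#' coordinates are shifted to the final contig. Sites must be distinct and
#' in-range. The six background bases flanking each repeat copy are forced
#' to mismatch their alignment-extension counterparts inside the element,
#' so the planted repeat pair is the unique maximal local alignment and
#' truth length/identity are exactly recoverable.
#'
#' @param genome One-row tibble from [generate_background()].
#' @param eves List of assembled elements from [assemble_eve()], each
#'   carrying `spec` (assign `x$spec <- spec` or use [simulate_genome()]).
#' @return List with `genome` (tibble) and `truth` (tibble with contig
#'   coordinates).
#' @export
plant_eves <- function(genome, eves) {
  stopifnot(nrow(genome) == 1)
  bg <- genome$seq
  n <- nchar(bg)
  if (!length(eves)) {
    return(list(genome = genome, truth = empty_truth()))
  }
  sites <- vapply(eves, function(e) {
    s <- e$spec$insertion_site
    if (is.infinite(s)) n + 1 else as.numeric(s)
  }, numeric(1))
  if (anyDuplicated(sites)) abort("overlapping insertions: duplicate sites")
  if (any(sites < 1 | sites > n + 1)) abort("insertion site out of range")
  ord <- order(sites)
  eves <- eves[ord]; sites <- sites[ord]
  pieces <- character(0)
  truths <- list()
  prev <- 1
  offset <- 0
  bg_chars <- strsplit(bg, "")[[1]]
  for (i in seq_along(eves)) {
    e <- eves[[i]]
    site <- sites[i]
    el_chars <- strsplit(e$seq, "")[[1]]
    el_len <- length(el_chars)
    tr <- e$truth
    # boundary sharpening against alignment extension (see docs)
    if (!is.na(tr$ltr3_start)) {
      for (k in 0:5) {
        # left of the pair: background vs interior tail before the 3' copy
        bpos <- site - 1 - k
        ipos <- tr$ltr3_start - 1 - k
        if (bpos >= 1 && ipos >= 1 && bg_chars[bpos] == el_chars[ipos]) {
          bg_chars[bpos] <- alt_base(el_chars[ipos])
        }
        # right of the pair: linker after the 5' copy vs background after
        bpos <- site + k            # first background positions after element
        ipos <- tr$ltr5_end + 1 + k
        if (bpos <= n && ipos <= el_len && bg_chars[bpos] == el_chars[ipos]) {
          bg_chars[bpos] <- alt_base(el_chars[ipos])
        }
      }
    }
    before <- if (site > prev) paste0(bg_chars[prev:(site - 1)], collapse = "") else ""
    pieces <- c(pieces, before, e$seq)
    start <- site + offset
    tr2 <- tr
    tr2$contig <- genome$id
    tr2$element_start <- as.integer(start)
    tr2$element_end <- as.integer(start + el_len - 1)
    for (col in c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                  "orf_start", "orf_end")) {
      tr2[[col]] <- as.integer(tr2[[col]] + start - 1L)
    }
    truths[[i]] <- tr2
    prev <- site
    offset <- offset + el_len
  }
  if (prev <= n) {
    pieces <- c(pieces, paste0(bg_chars[seq(prev, n)], collapse = ""))
  }
  seq2 <- paste0(pieces, collapse = "")
  list(
    genome = tibble(id = genome$id, seq = seq2, length = nchar(seq2)),
    truth = bind_rows(truths)
  )
}

alt_base <- function(b) {
  switch(b, A = "C", C = "A", G = "T", T = "G", N = "A", "A")
}

empty_truth <- function() {
  tibble(label = character(), disruption = character(),
         element_length = integer(), ltr_length = integer(),
         realized_ltr_identity = double(), ltr5_start = integer(),
         ltr5_end = integer(), ltr3_start = integer(), ltr3_end = integer(),
         orf_start = integer(), orf_end = integer(),
         polyprotein_length = integer(), rt_motif = character(),
         motif_pos = integer(), env_start = integer(), gn_start = integer(),
         gn_end = integer(), gc_start = integer(), gc_end = integer(),
         tm_starts = list(), gc_sequon = integer(), gc_cysteines = integer(),
         expected_verdict = character(), contig = character(),
         element_start = integer(), element_end = integer())
}

#' Simulate a genome with planted elements
#'
#' Convenience wrapper: background + [assemble_eve()] per spec +
#' [plant_eves()].
#'
#' @param specs List of [eve_spec()]s (insertion sites set).
#' @param bg_length Background length in nt.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @param id Contig id.
#' @param env_parts Optional shared envelope cassettes.
#' @return List `genome`, `truth`, `env_parts` (of the first coding
#'   element, for reuse), `elements` (assembled pieces).
#' @export
simulate_genome <- function(specs, bg_length = 50000, gc = 0.42, seed = 1,
                            id = "synthetic_contig", env_parts = NULL) {
  bg <- generate_background(bg_length, gc, seed, id)
  eves <- list()
  for (i in seq_along(specs)) {
    e <- assemble_eve(specs[[i]], seed = seed, env_parts = if (specs[[i]]$disruption == "solo_ltr") NULL else env_parts)
    if (is.null(env_parts) && !is.null(e$env_parts)) env_parts <- e$env_parts
    e$spec <- specs[[i]]
    eves[[i]] <- e
  }
  planted <- plant_eves(bg, eves)
  list(genome = planted$genome, truth = planted$truth,
       env_parts = env_parts, elements = eves)
}

#' Truth records as GFF3-ready features
#'
#' @param truth Truth tibble from [plant_eves()].
#' @return Feature tibble for [write_gff3()].
#' @export
truth_features <- function(truth) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    att <- list(label = t$label, disruption = t$disruption)
    rows[[length(rows) + 1]] <- tibble(
      seqid = t$contig, start = t$element_start, end = t$element_end,
      strand = "+", type = "element", attributes = list(att))
    rows[[length(rows) + 1]] <- tibble(
      seqid = t$contig, start = t$ltr5_start, end = t$ltr5_end,
      strand = "+", type = "LTR", attributes = list(att))
    if (!is.na(t$ltr3_start)) {
      rows[[length(rows) + 1]] <- tibble(
        seqid = t$contig, start = t$ltr3_start, end = t$ltr3_end,
        strand = "+", type = "LTR", attributes = list(att))
    }
    if (!is.na(t$orf_start)) {
      rows[[length(rows) + 1]] <- tibble(
        seqid = t$contig, start = t$orf_start, end = t$orf_end,
        strand = "+", type = "ORF", attributes = list(att))
    }
  }
  bind_rows(rows)
}
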