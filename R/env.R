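# Envelope architecture. Retroviral envelopes are single class-I (helical,
# heptad-bearing) glycoproteins with one C-terminal transmembrane (TM)
# anchor; phleboviruses instead cleave a precursor into tandem GN
# (receptor-binding) and GC (class-II fusion) glycoproteins, each with its
# own TM. This module decides which layout an Env region shows, from
# Kyte-Doolittle hydropathy, TM segment calls, N-glycosylation sequons and
# a cysteine census. Cleavage sites are approximated by region boundaries
# adjacent to TM segments; no protease-specificity model is attempted.

#' Kyte-Doolittle hydropathy index
#'
#' @return Named numeric vector over the 20 residues (X and `*` score 0).
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
    X = 0, "*" = 0)
}

#' Sliding-window hydropathy profile
#'
#' Centered sliding mean of Kyte-Doolittle values; at the termini the
#' window is truncated to the available residues.
#'
#' @param protein Amino-acid string.
#' @param window Odd window size, at least 7 (default 19, the canonical TM
#'   setting).
#' @return Tibble `position`, `hydropathy`.
#' @export
hydropathy_profile <- function(protein, window = 19) {
  stopifnot(window %% 2 == 1, window >= 7)
  kd <- kyte_doolittle()
  vals <- unname(kd[strsplit(toupper(protein), "")[[1]]])
  if (anyNA(vals)) abort("protein contains residues outside the 20+X+* alphabet")
  n <- length(vals)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, vals))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  tibble(position = seq_len(n), hydropathy = (cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of profile values at or above `threshold` with length at
#' least `min_len`; runs separated by fewer than `merge_within` residues
#' are merged first.
#'
#' @param profile Tibble from [hydropathy_profile()] (or a bare numeric
#'   vector of per-residue hydropathy).
#' @param threshold Hydropathy cutoff (default 1.6).
#' @param min_len Minimum segment length (default 17).
#' @param merge_within Merge runs separated by fewer than this many
#'   residues (default 5).
#' @return Tibble `start`, `end`, `mean_hydropathy`.
#' @export
predict_tm_segments <- function(profile, threshold = 1.6, min_len = 17,
                                merge_within = 5) {
  vals <- if (is.data.frame(profile)) profile$hydropathy else as.numeric(profile)
  empty <- tibble(start = integer(), end = integer(),
                  mean_hydropathy = double())
  above <- vals >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short dips
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      lastk <- keep[[length(keep)]]
      if (runs$start[i] - lastk$end < merge_within) {
        keep[[length(keep)]]$end <- runs$end[i]
      } else {
        keep[[length(keep) + 1]] <- runs[i, ]
      }
    }
    runs <- bind_rows(keep)
  }
  runs <- runs |> filter(.data$end - .data$start + 1 >= min_len)
  if (!nrow(runs)) return(empty)
  runs |>
    mutate(mean_hydropathy = purrr::map2_dbl(.data$start, .data$end,
                                             function(s, e) mean(vals[s:e])))
}

#' Scan for N-glycosylation sequons
#'
#' All N-X-[S/T] triplets with X not proline, reported by the 1-based
#' position of the asparagine.
#'
#' @param protein Amino-acid string.
#' @return Tibble `position`, `triplet`.
#' @export
scan_sequons <- function(protein) {
  protein <- toupper(protein)
  m <- gregexpr("(?=N[^P][ST])", protein, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(position = integer(), triplet = character()))
  tibble(position = as.integer(m),
         triplet = substring(protein, m, m + 2))
}

#' Count cysteines in a span
#'
#' @param protein Amino-acid string.
#' @param start,end 1-based inclusive span (defaults: whole protein). An
#'   empty span (`end < start`) counts 0.
#' @return Integer count.
#' @export
count_cysteines <- function(protein, start = 1, end = nchar(protein)) {
  if (start < 1 || end > nchar(protein)) abort("span out of protein bounds")
  if (end < start) return(0L)
  sum(strsplit(substr(toupper(protein), start, end), "")[[1]] == "C")
}

# Heptad-repeat score of an ectodomain: over all 7 phases and 28-residue
# windows, the best fraction of a/d heptad positions that are hydrophobic.
# Class I (retroviral) fusion subunits score high; beta-rich class II
# ectodomains do not.
heptad_score <- function(protein) {
  kd <- kyte_doolittle()
  vals <- kd[strsplit(toupper(protein), "")[[1]]]
  n <- length(vals)
  if (n < 28) return(0)
  hydro <- vals >= 1.8
  best <- 0
  for (phase in 0:6) {
    idx <- seq_len(n)
    ad <- ((idx - 1 - phase) %% 7) %in% c(0, 3)
    for (s in seq(1, n - 27)) {
      w <- s:(s + 27)
      sel <- w[ad[w]]
      if (length(sel) >= 7) best <- max(best, mean(hydro[sel]))
    }
  }
  best
}

#' Classify an envelope protein's architecture
#'
#' Decides between the phlebovirus-like tandem GN+GC layout and a
#' retrovirus-like single glycoprotein. The tandem call requires (a) a
#' GC-query hit occupying the C-terminal portion of the protein, (b) a
#' distinct upstream GN-like region (its own TM segment or a GN-query
#' hit), and (c) exactly one TM segment in the GC region, located
#' C-terminally. A retrovirus-like call requires a single TM with a
#' heptad-bearing ectodomain and no tandem-cassette evidence. Anything
#' else is unclassified. The call is deterministic and does not depend on
#' the order of the hit rows.
#'
#' @param protein Env amino-acid string (numbering local to this protein).
#' @param hits Tibble of homology hits on this protein with columns
#'   `role` (`"gn"`/`"gc"`), `start`, `end` (1-based residue spans). May be
#'   empty or NULL.
#' @param tm Optional precomputed TM tibble (else computed here).
#' @param window,threshold,min_len TM predictor settings.
#' @param gc_cterm_margin The GC TM must end within this many residues of
#'   the GC region end (default 60).
#' @param heptad_min Minimum heptad score for a retrovirus-like call.
#' @return One-row tibble: `class`, `gn_start`, `gn_end`, `gc_start`,
#'   `gc_end`, `n_tm`, `cysteine_count`, `n_sequons`, plus list-columns
#'   `tm` and `sequons`.
#' @export
classify_env <- function(protein, hits = NULL, tm = NULL, window = 19,
                         threshold = 1.6, min_len = 17,
                         gc_cterm_margin = 60, heptad_min = 0.8) {
  if (!nzchar(protein)) abort("empty env protein")
  L <- nchar(protein)
  if (is.null(tm)) {
    tm <- predict_tm_segments(hydropathy_profile(protein, window),
                              threshold = threshold, min_len = min_len)
  }
  tm <- tm |> arrange(.data$start)
  seqs <- scan_sequons(protein)
  hits <- if (is.null(hits)) tibble(role = character(), start = integer(),
                                    end = integer()) else
    hits |> arrange(.data$role, .data$start)
  gc_hits <- hits |> filter(.data$role == "gc")
  gn_hits <- hits |> filter(.data$role == "gn")
  gc <- c(NA_integer_, NA_integer_)
  gn <- c(NA_integer_, NA_integer_)
  klass <- "unclassified"

  if (nrow(gc_hits)) gc <- c(min(gc_hits$start), max(gc_hits$end))
  cond_a <- !is.na(gc[1]) && gc[2] >= L - 30 && gc[1] >= 60
  if (cond_a) {
    upstream_tm <- tm |> filter(.data$end < gc[1] + 10)
    cond_b <- nrow(upstream_tm) > 0 || (nrow(gn_hits) > 0 &&
                                          min(gn_hits$start) < gc[1])
    gc_tm <- tm |> filter(.data$end > gc[1])
    cond_c <- nrow(gc_tm) == 1 && gc_tm$end >= gc[2] - gc_cterm_margin
    if (cond_b && cond_c) {
      klass <- "phlebovirus_like_GN_GC"
      gn_end <- if (nrow(upstream_tm)) max(upstream_tm$end) else gc[1] - 1L
      gn_start <- if (nrow(gn_hits)) min(gn_hits$start) else 1L
      gn <- c(as.integer(gn_start), as.integer(gn_end))
      gc[1] <- max(gc[1], gn_end + 1L)
    }
  }
  if (klass == "unclassified" && nrow(tm) == 1 && tm$end >= L - gc_cterm_margin &&
      nrow(gc_hits) == 0) {
    ecto <- substr(protein, 1, max(1, tm$start - 1))
    if (heptad_score(ecto) >= heptad_min) klass <- "retrovirus_like"
  }
  tibble(
    class = klass,
    gn_start = gn[1], gn_end = gn[2], gc_start = gc[1], gc_end = gc[2],
    n_tm = nrow(tm),
    cysteine_count = count_cysteines(protein),
    n_sequons = nrow(seqs),
    tm = list(tm), sequons = list(seqs)
  )
}
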