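# Translated homology search: six-frame Smith-Waterman (or PSSM) scanning
# of a genome with protein queries, Karlin-Altschul bit scoring, and
# merging of neighbouring same-frame hits into candidate loci.
#
# E-values are deliberately not computed: they depend on the size of the
# database searched, so bit-score plus aligned-length thresholds take their
# place for locus seeding.

#' Karlin-Altschul bit score
#'
#' Normalizes a raw alignment score so thresholds are matrix independent:
#' `bits = (lambda * raw - ln K) / ln 2`. Defaults are the community gapped
#' constants for BLOSUM62 with gap costs 11/1.
#'
#' @param raw Raw alignment score(s).
#' @param lambda,K Karlin-Altschul parameters (`lambda > 0`, `K > 0`).
#' @return Bit score(s).
#' @export
bit_score <- function(raw, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0)
  (lambda * raw - log(K)) / log(2)
}

#' Build a position-specific scoring matrix from a seed alignment
#'
#' Per-column log-odds of residue frequency against the BLOSUM62 background,
#' in half-bit units, with substitution-matrix pseudocounts: the pseudocount
#' distribution of a column is the BLOSUM62-implied conditional residue
#' distribution of its observed residues, so as `pseudocount` grows the
#' column scores approach the substitution scores of the observed residue.
#' Columns with more than 50% gap characters are dropped from the model.
#'
#' @param alignment Character vector of equal-length aligned rows (gaps `-`).
#' @param pseudocount Positive pseudocount weight (default 1).
#' @param matrix Substitution matrix used for the background and the
#'   pseudocount distribution.
#' @return An object of class `pssm`: list with `scores` (L x 20 matrix,
#'   half-bits), `positions` (kept column indices of the input alignment),
#'   `pseudocount`.
#' @export
build_pssm <- function(alignment, pseudocount = 1, matrix = blosum62()) {
  stopifnot(length(alignment) >= 1, pseudocount > 0)
  alignment <- toupper(alignment)
  L <- unique(nchar(alignment))
  if (length(L) != 1) abort("ragged alignment: rows differ in length")
  res <- names(blosum62_background())
  bg <- blosum62_background()
  # P(a | r) implied by the half-bit matrix: bg_a * 2^(M[r,a]/2), normalized
  cond <- t(vapply(res, function(r) {
    p <- bg * 2^(matrix[r, res] / 2)
    p / sum(p)
  }, numeric(20)))
  rownames(cond) <- res
  rows <- do.call(rbind, strsplit(alignment, ""))
  keep <- which(colMeans(rows == "-") <= 0.5)
  if (!length(keep)) abort("no columns with <= 50% gaps")
  scores <- matrix(NA_real_, length(keep), 20, dimnames = list(NULL, res))
  for (k in seq_along(keep)) {
    col <- rows[, keep[k]]
    col <- col[col != "-"]
    col[!col %in% res] <- NA
    col <- col[!is.na(col)]
    counts <- table(factor(col, levels = res))
    Nn <- sum(counts)
    g <- if (Nn > 0) colSums(cond[res, , drop = FALSE] * as.numeric(counts) / Nn) else bg
    f <- (as.numeric(counts) + pseudocount * g) / (Nn + pseudocount)
    scores[k, ] <- 2 * log2(f / bg)
  }
  structure(list(scores = scores, positions = keep, pseudocount = pseudocount),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> ", nrow(x$scores), " positions, pseudocount ",
      x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' Serialize / read a PSSM as TSV
#'
#' TSV with a `pos` column and one column per residue.
#' @param pssm A `pssm` object.
#' @param path File path.
#' @return `path` (write) or a `pssm` (read).
#' @export
write_pssm <- function(pssm, path) {
  df <- as.data.frame(pssm$scores)
  df <- cbind(pos = pssm$positions, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  scores <- as.matrix(df[, -1])
  structure(list(scores = scores, positions = df$pos, pseudocount = NA_real_),
            class = "pssm")
}

# Extend a scoring matrix for PSSM scanning: one row per model position,
# columns in the order of the protein scoring alphabet (X, * and the
# ambiguity letters score a flat penalty).
pssm_score_matrix <- function(pssm, alpha) {
  out <- matrix(-1, nrow(pssm$scores), length(alpha),
                dimnames = list(NULL, alpha))
  out[, colnames(pssm$scores)] <- pssm$scores
  out[, "*"] <- -4
  out
}

#' Scan a genome with a protein query or PSSM
#'
#' Searches all six reading frames of every contig by exact local alignment
#' and reports every hit above the raw-score floor implied by `min_bits`.
#' Within one (contig, frame) the search repeatedly extracts the best
#' alignment and masks it, so multiple elements on one contig are all found.
#'
#' @param genome Tibble with `id`, `seq` (nucleotide), e.g. from
#'   [read_fasta()] or [generate_background()].
#' @param query A protein tibble row set (`id`, `seq`) or a [build_pssm()]
#'   object.
#' @param matrix Substitution matrix (ignored for PSSM queries except as
#'   alphabet source).
#' @param gap_open,gap_extend Affine gap costs.
#' @param min_bits,min_aligned Reporting thresholds: minimum bit score and
#'   minimum aligned columns.
#' @param lambda,K Karlin-Altschul constants for [bit_score()].
#' @param max_hits_per_frame Safety cap on hits extracted per contig/frame.
#' @return Tibble of hits sorted by bits descending (ties by contig, start):
#'   `query`, `contig`, `frame` (+1..+3, -1..-3), `t_start`, `t_end`
#'   (1-based nucleotide span on the forward strand), `q_start`, `q_end`,
#'   `raw`, `bits`, `identity_pct`, `aligned_length`, `q_aln`, `t_aln`.
#' @export
scan_genome <- function(genome, query, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1, min_bits = 50, min_aligned = 80,
                        lambda = 0.267, K = 0.041,
                        max_hits_per_frame = 64) {
  is_pssm <- inherits(query, "pssm")
  alpha <- rownames(matrix)
  if (is_pssm) {
    S <- pssm_score_matrix(query, alpha)
    queries <- tibble(id = "pssm", seq = NA_character_)
  } else {
    S <- matrix
    queries <- query
  }
  min_raw <- (min_bits * log(2) + log(K)) / lambda
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    qid <- queries$id[qi]
    if (is_pssm) {
      av <- seq_len(nrow(query$scores))
      qlen <- length(av)
      qseq <- NULL
    } else {
      qseq <- toupper(queries$seq[qi])
      av <- encode_seq(qseq, alpha)
      qlen <- length(av)
    }
    for (gi in seq_len(nrow(genome))) {
      contig <- genome$id[gi]
      len <- nchar(genome$seq[gi])
      frames <- six_frame(genome$seq[gi])
      for (fi in seq_len(nrow(frames))) {
        aa <- frames$aa[fi]
        if (!nzchar(aa)) next
        bv <- encode_seq(aa, alpha)
        hits <- c_local_align_multi(av, bv, S, gap_open, gap_extend,
                                    min_raw, max_hits_per_frame,
                                    qlen, qlen + 1500L)
        for (h in hits) {
          if (length(h$a_idx) < min_aligned) next
          nt <- frame_to_nt(frames$frame[fi], h$b_start, h$b_end, len)
          strs <- aln_strings(if (is_pssm) strrep("X", qlen) else qseq,
                              aa, h$a_idx, h$b_idx)
          idn <- if (is_pssm) {
            list(pct = NA_real_)
          } else {
            aln_identity(qseq, aa, h$a_idx, h$b_idx)
          }
          out[[length(out) + 1]] <- tibble(
            query = qid, contig = contig, frame = frames$frame[fi],
            t_start = nt[1], t_end = nt[2],
            q_start = h$a_start, q_end = h$a_end,
            raw = h$score, bits = bit_score(h$score, lambda, K),
            identity_pct = idn$pct,
            aligned_length = length(h$a_idx),
            q_aln = strs$a, t_aln = strs$b
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(query = character(), contig = character(), frame = integer(),
                  t_start = integer(), t_end = integer(), q_start = integer(),
                  q_end = integer(), raw = double(), bits = double(),
                  identity_pct = double(), aligned_length = integer(),
                  q_aln = character(), t_aln = character()))
  }
  bind_rows(out) |>
    arrange(desc(.data$bits), .data$contig, .data$t_start)
}

#' Merge neighbouring hits into candidate loci
#'
#' Hits on the same contig whose nucleotide spans are within `merge_gap` of
#' each other are merged into one locus (envelope cassettes may align in
#' pieces, and separate GN/GC queries hit adjacent spans of one element).
#' By default merging is frame-aware only within a query; hits from
#' different queries on the same contig merge across frames when adjacent.
#'
#' @param hits Hit tibble from [scan_genome()] (possibly several queries
#'   bound together).
#' @param merge_gap Maximum nucleotide gap bridged (default 1000).
#' @param same_frame_only If `TRUE`, only hits in the identical frame merge.
#' @return Tibble of loci: `contig`, `start`, `end`, `n_hits`, `best_bits`,
#'   `strand`, and a list-column `hits` with the member hits.
#' @export
merge_hits <- function(hits, merge_gap = 1000, same_frame_only = FALSE) {
  if (!nrow(hits)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  n_hits = integer(), best_bits = double(),
                  strand = character(), hits = list()))
  }
  key <- if (same_frame_only) {
    paste(hits$contig, hits$frame)
  } else {
    paste(hits$contig, ifelse(hits$frame > 0, "+", "-"))
  }
  out <- list()
  for (k in unique(key)) {
    grp <- hits[key == k, ] |> arrange(.data$t_start)
    cur <- grp[1, ]
    members <- list(grp[1, ])
    flushed <- function(cur, members) {
      m <- bind_rows(members)
      tibble(contig = cur$contig, start = min(m$t_start), end = max(m$t_end),
             n_hits = nrow(m), best_bits = max(m$bits),
             strand = if (m$frame[which.max(m$bits)] > 0) "+" else "-",
             hits = list(m))
    }
    if (nrow(grp) > 1) {
      lo <- grp$t_start[1]; hi <- grp$t_end[1]
      for (i in 2:nrow(grp)) {
        if (grp$t_start[i] <= hi + merge_gap) {
          hi <- max(hi, grp$t_end[i])
          members <- c(members, list(grp[i, ]))
        } else {
          out[[length(out) + 1]] <- flushed(cur, members)
          members <- list(grp[i, ]); lo <- grp$t_start[i]; hi <- grp$t_end[i]
        }
      }
    }
    out[[length(out) + 1]] <- flushed(cur, members)
  }
  bind_rows(out) |> arrange(.data$contig, .data$start)
}
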