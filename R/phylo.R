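# Phylogenetic placement of candidate reverse transcriptases (and GC-like
# envelope sequences): k-mer guide distances, guide-tree progressive
# alignment with profile-profile merging over the same scoring machinery as
# the homology search, Poisson-corrected distances, and neighbor joining.
# NJ is used rather than maximum likelihood because the testable claims are
# nearest-neighbor relations, which are robust to method at these
# divergences; tie-breaking is deterministic everywhere so trees reproduce
# bit for bit.

# fraction of shared k-mers -> distance in [0, 1]
kmer_distance <- function(seqs, k = 3) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      denom <- min(length(sets[[i]]), length(sets[[j]]))
      d[i, j] <- d[j, i] <- if (denom == 0) 1 else 1 - inter / denom
    }
  }
  d
}

# profile = L x (21) column frequency matrix over residues + "-"
seq_to_profile <- function(aligned, res) {
  rows <- do.call(rbind, strsplit(aligned, ""))
  t(apply(rows, 2, function(col) {
    tab <- table(factor(col, levels = c(res, "-")))
    as.numeric(tab) / length(col)
  }))
}

profile_cell_scores <- function(pa, pb, matrix, res, gap_cost) {
  A <- pa[, seq_along(res), drop = FALSE]
  B <- pb[, seq_along(res), drop = FALSE]
  M <- matrix[res, res]
  cells <- A %*% M %*% t(B)
  # gap characters inside a profile column pay a flat per-column cost
  ga <- pa[, length(res) + 1]
  gb <- pb[, length(res) + 1]
  cells - gap_cost * outer(ga, gb, "+")
}

align_profiles <- function(a, b, matrix, res, gap_open, gap_extend) {
  pa <- seq_to_profile(a$aligned, res)
  pb <- seq_to_profile(b$aligned, res)
  cells <- profile_cell_scores(pa, pb, matrix, res, gap_cost = 1)
  aln <- c_global_align_cells(cells, gap_open, gap_extend)
  expand <- function(rows, idx) {
    vapply(rows, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste0(ifelse(idx > 0, ch[pmax(idx, 1)], "-"), collapse = "")
    }, character(1))
  }
  list(ids = c(a$ids, b$ids),
       aligned = c(expand(a$aligned, aln$a_idx), expand(b$aligned, aln$b_idx)))
}

#' Progressive multiple alignment
#'
#' Pairwise k-mer distances give an average-linkage guide tree; profiles
#' are merged bottom-up by profile-profile global alignment under the same
#' substitution model as the homology search. Deterministic: at each merge
#' the two profiles are ordered by their lexicographically smallest member
#' id, so the output does not depend on input order.
#'
#' @param seqs Tibble with `id`, `seq` (proteins), or named character
#'   vector; at least 2 sequences.
#' @param matrix,gap_open,gap_extend Scoring (defaults BLOSUM62, 11/1).
#' @param k k-mer size for guide distances.
#' @return Tibble `id`, `aligned` (equal-length rows, gaps `-`), in input
#'   order; class `msa_tbl`.
#' @export
progressive_align <- function(seqs, matrix = blosum62(), gap_open = 11,
                              gap_extend = 1, k = 3) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (length(seqs) < 2) abort("need at least 2 sequences to align")
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  names(seqs) <- ids
  seqs <- toupper(seqs)
  res <- names(blosum62_background())
  ord <- order(ids)                      # canonical processing order
  d <- kmer_distance(seqs[ord], k)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profiles <- lapply(ord, function(i) list(ids = ids[i], aligned = unname(seqs[i])))
  merged <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) profiles[[-v]] else merged[[v]]
    a <- pick(hc$merge[s, 1]); b <- pick(hc$merge[s, 2])
    if (min(a$ids) > min(b$ids)) { tmp <- a; a <- b; b <- tmp }
    merged[[s]] <- align_profiles(a, b, matrix, res, gap_open, gap_extend)
  }
  final <- if (nrow(hc$merge)) merged[[nrow(hc$merge)]] else profiles[[1]]
  out <- tibble(id = unname(final$ids), aligned = unname(final$aligned))
  out <- out[match(ids, out$id), ]
  class(out) <- c("msa_tbl", class(out))
  out
}

#' Poisson-corrected distance between two aligned rows
#'
#' p = mismatches over shared ungapped columns; d = -ln(1 - p). Gapped
#' columns are excluded pairwise (not listwise), so fragments of unequal
#' coverage still yield distances. p = 1 maps to `max_distance`.
#'
#' @param row_i,row_j Equal-length aligned strings.
#' @param max_distance Declared maximum for saturated pairs (default 10).
#' @return Substitutions per site.
#' @export
corrected_distance <- function(row_i, row_j, max_distance = 10) {
  a <- strsplit(toupper(row_i), "")[[1]]
  b <- strsplit(toupper(row_j), "")[[1]]
  stopifnot(length(a) == length(b))
  shared <- a != "-" & b != "-"
  if (!any(shared)) abort("no shared ungapped columns")
  p <- mean(a[shared] != b[shared])
  if (p >= 1) return(max_distance)
  min(-log(1 - p), max_distance)
}

#' Pairwise corrected distance matrix of an alignment
#'
#' @param msa Tibble from [progressive_align()] (columns `id`, `aligned`).
#' @param max_distance Passed to [corrected_distance()].
#' @return Symmetric matrix of substitutions per site, zero diagonal.
#' @export
msa_distances <- function(msa, max_distance = 10) {
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- corrected_distance(msa$aligned[i], msa$aligned[j],
                                               max_distance)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ (exact on additive matrices); negative branch-length
#' estimates are clamped to zero and reported via a message.
#'
#' @param D Symmetric distance matrix with taxon dimnames, n >= 3.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) < 3) abort("need a distance matrix with n >= 3")
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Nearest leaf by patristic distance
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param taxon Query leaf label.
#' @return One-row tibble `taxon`, `neighbor`, `distance`, `tied` (other
#'   leaves at the same minimal distance, alphabetical, as one
#'   comma-separated string or NA). Ties are broken alphabetically.
#' @export
nearest_neighbor <- function(tree, taxon) {
  if (!taxon %in% tree$tip.label) abort(paste0("unknown taxon: ", taxon))
  pd <- stats::cophenetic(tree)[taxon, ]
  pd <- pd[names(pd) != taxon]
  minval <- min(pd)
  cands <- sort(names(pd)[abs(pd - minval) < 1e-12])
  tibble(taxon = taxon, neighbor = cands[1], distance = minval,
         tied = if (length(cands) > 1) paste(cands[-1], collapse = ",") else NA_character_)
}

#' Build an RT (or GC) tree from protein sequences
#'
#' Convenience chain: [progressive_align()] -> [msa_distances()] ->
#' [neighbor_joining()].
#'
#' @param seqs Tibble `id`, `seq` or named character vector (3+ proteins).
#' @param ... Passed to [progressive_align()].
#' @return List with `msa`, `distances`, `tree`.
#' @export
build_tree <- function(seqs, ...) {
  msa <- progressive_align(seqs, ...)
  D <- msa_distances(msa)
  list(msa = msa, distances = D, tree = neighbor_joining(D))
}
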