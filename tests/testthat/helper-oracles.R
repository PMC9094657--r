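# Independent naive oracles used across the suite. Everything here is
# deliberately written by the most direct route available (loops,
# enumeration, closed forms) and shares no code with the package
# implementations it checks.

# Affine global alignment score by a plain three-state DP written
# independently of the package engine. Gap of length k costs
# go + (k - 1) * ge.
oracle_global_score <- function(a, b, S, go, ge) {
  m <- length(a); n <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1, 1] <- -(go + (i - 1) * ge)
  for (j in seq_len(n)) Y[1, j + 1] <- -(go + (j - 1) * ge)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- S[a[i], b[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - ge,
                             Y[i, j + 1] - go)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, X[i + 1, j] - go,
                             Y[i + 1, j] - ge)
    }
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# Brute-force local alignment score: enumerate every substring pair and
# score each end-to-end; the best positive value is the local optimum.
oracle_local_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  m <- length(av); n <- length(bv)
  for (i1 in seq_len(m)) for (i2 in i1:m) {
    for (j1 in seq_len(n)) for (j2 in j1:n) {
      sc <- oracle_global_score(av[i1:i2], bv[j1:j2], S, go, ge)
      if (sc > best) best <- sc
    }
  }
  best
}

# Exhaustive recursion over every gapped alignment of a vs b (tiny inputs
# only), tracking the previous move for affine costs. Independent
# cross-check of oracle_global_score.
oracle_enumerate_global <- function(a, b, S, go, ge) {
  # enumerate columns right-to-left; a gap column pays ge when the column
  # to its right is a gap in the same sequence (so each run costs
  # go + (k - 1) * ge with the opening charge at its right end)
  rec <- function(i, j, nxt) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j - 1, "M") + S[a[i], b[j]])
    if (i > 0) best <- max(best, rec(i - 1, j, "X") -
                             (if (nxt == "X") ge else go))
    if (j > 0) best <- max(best, rec(i, j - 1, "Y") -
                             (if (nxt == "Y") ge else go))
    best
  }
  rec(length(a), length(b), "M")
}

random_protein <- function(n, residues = c("A", "R", "N", "D", "C", "Q",
                                           "E", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V")) {
  paste0(sample(residues, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sequons by explicit loop
naive_sequons <- function(p) {
  ch <- strsplit(p, "")[[1]]
  out <- integer(0)
  if (length(ch) >= 3) {
    for (i in 1:(length(ch) - 2)) {
      if (ch[i] == "N" && ch[i + 1] != "P" && ch[i + 2] %in% c("S", "T")) {
        out <- c(out, i)
      }
    }
  }
  out
}

# first Y-X-D-[D/N] in a span by explicit loop
naive_motif <- function(p, from, to) {
  ch <- strsplit(p, "")[[1]]
  for (i in from:min(to, length(ch) - 3)) {
    if (ch[i] == "Y" && ch[i + 2] == "D" && ch[i + 3] %in% c("D", "N")) {
      return(i)
    }
  }
  NA_integer_
}

# windowed hydropathy mean by explicit loop
naive_hydropathy <- function(p, window) {
  kd <- kyte_doolittle()
  v <- kd[strsplit(p, "")[[1]]]
  half <- (window - 1) / 2
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    w <- max(1, i - half):min(length(v), i + half)
    out[i] <- mean(v[w])
  }
  out
}

# identity of two equal-length gapless strings by position count
naive_identity <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  100 * sum(a == b) / length(a)
}

# substitute exactly k positions of a sequence, spaced at least 5 apart so
# that no gapped alignment can outscore the ungapped column-count identity
substitute_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  cand <- seq(2, length(ch) - 1, by = 5)
  pos <- sample(cand, k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste0(ch, collapse = "")
}
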