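test_that("identical sequences align gap-free at 100% identity", {
  m <- progressive_align(c(a = "MKVLAT", b = "MKVLAT"))
  expect_equal(m$aligned, c("MKVLAT", "MKVLAT"))
  d <- corrected_distance(m$aligned[1], m$aligned[2])
  expect_equal(d, 0)
  expect_error(progressive_align(c(a = "MKV")), "at least 2")
})

test_that("a single-residue indel is placed as one gap column", {
  m <- progressive_align(c(a = "ACDEFG", b = "ACEFG"))
  expect_equal(m$aligned[m$id == "a"], "ACDEFG")
  expect_equal(m$aligned[m$id == "b"], "AC-EFG")
})

test_that("alignment does not depend on input order", {
  set.seed(51)
  base <- random_protein(60)
  seqs <- c(x = base,
            y = paste0(substr(base, 1, 30), random_protein(5),
                       substr(base, 31, 60)),
            z = random_protein(58))
  m1 <- progressive_align(seqs)
  m2 <- progressive_align(seqs[c(3, 1, 2)])
  m2 <- m2[match(m1$id, m2$id), ]
  expect_equal(m1$aligned, m2$aligned)
})

test_that("Poisson correction evaluates its closed forms and bound", {
  expect_equal(corrected_distance("AAAA", "AAAA"), 0)
  expect_equal(corrected_distance("AABB", "AACC"), -log(1 - 0.5))
  expect_equal(corrected_distance("AB", "BA", max_distance = 10), 10)
  expect_error(corrected_distance("--", "AA"), "shared")
  set.seed(52)
  for (i in 1:40) {
    a <- random_protein(30); b <- random_protein(30)
    sh <- strsplit(a, "")[[1]] != strsplit(b, "")[[1]]
    p <- mean(sh)
    if (p < 1) expect_gte(corrected_distance(a, b), p)
  }
})

test_that("NJ recovers additive matrices exactly and clamps degenerate ones", {
  set.seed(53)
  for (i in 1:30) {
    tr <- ape::rtree(sample(4:10, 1))
    D <- stats::cophenetic(tr)
    nj2 <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(tr, nj2), 0)
    expect_equal(stats::cophenetic(nj2)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  # star geometry: all internal branch lengths 0
  D <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  star <- suppressMessages(neighbor_joining(D))
  internal <- star$edge[, 2] > ape::Ntip(star)
  expect_true(all(star$edge.length[internal] < 1e-12))
  expect_error(neighbor_joining(D[1:2, 1:2]), "n >= 3")
})

test_that("nearest neighbors agree with brute-force path sums", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:5);")
  expect_equal(nearest_neighbor(tr, "a")$neighbor, "b")
  expect_equal(nearest_neighbor(tr, "b")$neighbor, "a")
  expect_error(nearest_neighbor(tr, "zz"), "unknown taxon")
  set.seed(54)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    D <- stats::cophenetic(tr)
    taxon <- sample(tr$tip.label, 1)
    ref <- names(which.min(D[taxon, setdiff(tr$tip.label, taxon)]))
    nn <- nearest_neighbor(tr, taxon)
    expect_equal(nn$distance, min(D[taxon, setdiff(tr$tip.label, taxon)]))
    expect_true(nn$neighbor %in%
                  names(which(abs(D[taxon, ] - nn$distance) < 1e-12)))
  }
})

test_that("Newick serialization round-trips topology and branch lengths", {
  set.seed(55)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    f <- withr::local_tempfile(fileext = ".nwk")
    ape::write.tree(tr, f)
    back <- ape::read.tree(f)
    expect_equal(phangorn::RF.dist(tr, back), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("the simulated RT family places the sister taxon nearest", {
  panel <- rt_panel(seed = 3)
  res <- build_tree(panel)
  expect_equal(sort(res$tree$tip.label), sort(panel$id))
  nn <- nearest_neighbor(res$tree, "Atlas_RT")
  expect_equal(nn$neighbor, "Cer13_RT")
})
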