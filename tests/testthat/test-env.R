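test_that("hydropathy profile reproduces the published index and symmetry", {
  prof <- hydropathy_profile(strrep("I", 30), window = 19)
  # every full-window position averages the isoleucine index
  expect_true(all(abs(prof$hydropathy[10:21] - 4.5) < 1e-12))
  expect_true(all(hydropathy_profile(strrep("E", 40))$hydropathy < 0))
  set.seed(41)
  for (i in 1:10) {
    p <- random_protein(sample(25:80, 1))
    rp <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
    expect_equal(hydropathy_profile(rp)$hydropathy,
                 rev(hydropathy_profile(p)$hydropathy))
  }
  expect_error(hydropathy_profile("ACD", window = 8), "window")
})

test_that("hydropathy profile equals the naive windowed mean", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_protein(sample(10:100, 1))
    w <- sample(c(7, 11, 19), 1)
    expect_equal(hydropathy_profile(p, w)$hydropathy, naive_hydropathy(p, w),
                 ignore_attr = TRUE)
  }
})

test_that("TM prediction finds planted hydrophobic stretches and no more", {
  set.seed(43)
  polar <- c("D", "E", "K", "S", "T", "G", "Q", "R")
  mk_polar <- function(n) paste0(sample(polar, n, TRUE), collapse = "")
  tm23 <- function() paste0(sample(c("L", "I", "V", "F"), 23, TRUE),
                            collapse = "")
  prot <- paste0(mk_polar(80), "SGTS", tm23(), "STGS", mk_polar(100),
                 "SGTS", tm23(), "STGS", mk_polar(60))
  segs <- predict_tm_segments(hydropathy_profile(prot))
  expect_equal(nrow(segs), 2)
  # planted TMs start at 85 and 216; calls within half a window
  expect_lt(abs(segs$start[1] - 85), 10)
  expect_lt(abs(segs$start[2] - 216), 10)
  # soluble construct: nothing called
  expect_equal(nrow(predict_tm_segments(hydropathy_profile(mk_polar(300)))), 0)
})

test_that("sequon scanning applies the N-X-[S/T], X != P rule", {
  expect_equal(scan_sequons("ANASA")$position, 2L)
  expect_equal(nrow(scan_sequons("ANPSA")), 0)
  expect_equal(scan_sequons("NNSS")$position, c(1L, 2L))  # overlapping hits
  set.seed(44)
  for (i in 1:300) {
    p <- random_protein(sample(5:80, 1))
    expect_equal(scan_sequons(p)$position, naive_sequons(p))
  }
})

test_that("cysteine counting respects spans and bounds", {
  expect_equal(count_cysteines("CACA"), 2L)
  expect_equal(count_cysteines("CACA", 2, 1), 0L)
  expect_equal(count_cysteines("CACA", 2, 4), 1L)
  expect_error(count_cysteines("CACA", 0, 4), "bounds")
  expect_error(count_cysteines("CACA", 1, 5), "bounds")
})

test_that("tandem GN+GC architecture is recognized with truthful spans", {
  al <- atlas_like_locus(seed = 5)
  t <- al$truth
  # analyze the true Env region of the planted polyprotein
  e <- al$genome$seq
  orf <- longest_orf(e, min_codons = 1000)
  env_prot <- substr(orf$protein, t$env_start, t$polyprotein_length)
  off <- t$env_start - 1
  hits <- tibble::tibble(
    role = c("gn", "gc"),
    start = c(t$gn_start, t$gc_start) - off,
    end = c(t$gn_end, t$gc_end) - off)
  arch <- classify_env(env_prot, hits = hits)
  expect_equal(arch$class, "phlebovirus_like_GN_GC")
  expect_lt(abs(arch$gc_start - (t$gc_start - off)), 30)
  expect_equal(arch$n_tm, 2L)
  # hit order does not matter
  arch2 <- classify_env(env_prot, hits = hits[2:1, ])
  expect_equal(arch2$class, arch$class)
  expect_equal(arch2$gc_start, arch$gc_start)
})

test_that("a single-TM envelope without GC evidence is not phlebovirus-like", {
  set.seed(45)
  polar <- c("D", "E", "K", "S", "T", "G", "Q", "R")
  ecto <- paste0(sample(polar, 400, TRUE), collapse = "")
  tm <- paste0(sample(c("L", "I", "V", "F"), 23, TRUE), collapse = "")
  prot <- paste0(ecto, "SGTS", tm, "STGS")
  arch <- classify_env(prot, hits = NULL)
  expect_false(arch$class == "phlebovirus_like_GN_GC")
})
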