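# Canned study designs built on the generator: the default planted
# benchmark (intact elements across an LTR-divergence grid plus every
# decoy class), a synthetic locus reproducing the published intact-element
# anatomy, a synthetic multi-contig assembly emulating the published
# nine-element composition, and a simulated RT panel for the phylogeny.
# All are deterministic functions of one seed.

#' Default planted benchmark genome
#'
#' Two contigs, 20 planted loci: 10 intact elements with 271-nt LTRs at
#' divergences 0 (x4), 0.02 (x3) and 0.05 (x3), and 10 decoys — two each
#' of internal_stop, frameshift, ltr_degeneration, solo_ltr and
#' ltr_truncation (the truncated elements sit at contig ends, where
#' assemblies clip repeats). All coding elements share one envelope
#' cassette family, whose GN and GC proteins are returned as the screen
#' queries; Gag and Pol are drawn per element.
#'
#' @param seed Integer seed.
#' @param gc Background GC fraction (default 0.42).
#' @return List: `genome` (2-contig tibble), `truth`, `queries` (GN/GC
#'   protein tibble with roles), `specs`.
#' @export
benchmark_genome <- function(seed = 1, gc = 0.42) {
  intact <- function(div, lab) {
    eve_spec(ltr_divergence = div, label = lab, gc = gc)
  }
  decoy <- function(kind, lab) {
    if (kind == "solo_ltr") {
      eve_spec(orf_length = 0, disruption = "solo_ltr", label = lab, gc = gc)
    } else {
      eve_spec(disruption = kind, label = lab, gc = gc)
    }
  }
  specs_a <- list(
    intact(0, "intact0_a"), decoy("internal_stop", "istop_a"),
    intact(0, "intact0_b"), decoy("ltr_degeneration", "degen_a"),
    decoy("solo_ltr", "solo_a"), intact(0.02, "intact2_a"),
    decoy("frameshift", "fshift_a"), intact(0.05, "intact5_a"),
    intact(0, "intact0_c"), decoy("ltr_degeneration", "degen_b"),
    intact(0.02, "intact2_b"), decoy("solo_ltr", "solo_b"),
    intact(0.05, "intact5_b"), decoy("frameshift", "fshift_b"),
    intact(0, "intact0_d"), decoy("internal_stop", "istop_b"),
    intact(0.02, "intact2_c"), intact(0.05, "intact5_c")
  )
  for (i in seq_along(specs_a)) {
    specs_a[[i]]$insertion_site <- 3000 + (i - 1) * 4000
  }
  trunc_a <- decoy("ltr_truncation", "trunc_a"); trunc_a$insertion_site <- Inf
  specs_a <- c(specs_a, list(trunc_a))
  sim_a <- simulate_genome(specs_a, bg_length = 75000, gc = gc,
                           seed = substream_seed(seed, "contigA"),
                           id = "contig_A")
  trunc_b <- decoy("ltr_truncation", "trunc_b"); trunc_b$insertion_site <- Inf
  sim_b <- simulate_genome(list(trunc_b), bg_length = 6000, gc = gc,
                           seed = substream_seed(seed, "contigB"),
                           id = "contig_B", env_parts = sim_a$env_parts)
  genome <- bind_rows(sim_a$genome, sim_b$genome)
  truth <- bind_rows(sim_a$truth, sim_b$truth)
  list(genome = genome, truth = truth,
       queries = env_queries_from_parts(sim_a$env_parts),
       specs = c(specs_a, list(trunc_b)))
}

env_queries_from_parts <- function(env_parts) {
  tibble(id = c("GN_query", "GC_query"),
         seq = c(env_parts$gn$seq, env_parts$gc$seq),
         role = c("gn", "gc"))
}

#' Synthetic locus with the published intact-element anatomy
#'
#' A synthetic stand-in (not the public accession) built to the published
#' signature of the intact reference element: 100% identical 271-nt LTRs,
#' a 9204-nt element encoding a 2828-residue polyprotein, YVDN polymerase
#' motif, envelope cassettes at polyprotein 1909-2329 (GN-like) and
#' 2330-2828 (GC-like), one C-terminal TM in GC, a single sequon at GC
#' position 414, and 30 cysteines in GC 1-443.
#'
#' @param seed Integer seed.
#' @param flank Background flank on each side of the element (nt).
#' @return List: `genome` (one contig holding the flanked element),
#'   `truth`, `queries`, `element` (element-only sequence).
#' @export
atlas_like_locus <- function(seed = 1, flank = 2100) {
  spec <- eve_spec(
    ltr_length = 271, ltr_divergence = 0, orf_length = 2828,
    rt_motif = "YVDN", env_tm_count = 2,
    gag_len = 950, pol_len = 958, gn_len = 421, gc_len = 499,
    linker5 = 100, linker3 = 75, label = "atlas_like"
  )
  spec$insertion_site <- flank + 1
  sim <- simulate_genome(list(spec), bg_length = 2 * flank, gc = 0.42,
                         seed = substream_seed(seed, "atlas_like"),
                         id = "atlas_like_synthetic")
  list(genome = sim$genome, truth = sim$truth,
       queries = env_queries_from_parts(sim$env_parts),
       element = sim$elements[[1]]$seq)
}

#' Synthetic assembly emulating the published nine-element composition
#'
#' A multi-contig genome carrying nine complete-polyprotein elements —
#' seven with intact LTR pairs, one with degenerate LTRs and one with an
#' assembly-truncated LTR — plus disrupted decoys, mirroring the
#' composition of the published element table.
#'
#' @param seed Integer seed.
#' @return As [benchmark_genome()].
#' @export
nine_eve_assembly <- function(seed = 1) {
  gc <- 0.42
  mk <- function(div, lab) eve_spec(ltr_divergence = div, label = lab, gc = gc)
  specs_a <- list(
    mk(0, "eve1"), eve_spec(disruption = "internal_stop", label = "d_istop", gc = gc),
    mk(0, "eve2"), mk(0.02, "eve3"),
    eve_spec(orf_length = 0, disruption = "solo_ltr", label = "d_solo", gc = gc),
    mk(0.01, "eve4"), eve_spec(disruption = "ltr_degeneration", label = "eve8_degen", gc = gc),
    mk(0.03, "eve5")
  )
  for (i in seq_along(specs_a)) specs_a[[i]]$insertion_site <- 2500 + (i - 1) * 4000
  sim_a <- simulate_genome(specs_a, bg_length = 35000, gc = gc,
                           seed = substream_seed(seed, "nineA"), id = "scf_1")
  specs_b <- list(
    mk(0, "eve6"), eve_spec(disruption = "frameshift", label = "d_fshift", gc = gc),
    mk(0.02, "eve7")
  )
  for (i in seq_along(specs_b)) specs_b[[i]]$insertion_site <- 2500 + (i - 1) * 4000
  trunc <- eve_spec(disruption = "ltr_truncation", label = "eve9_trunc", gc = gc)
  trunc$insertion_site <- Inf
  specs_b <- c(specs_b, list(trunc))
  sim_b <- simulate_genome(specs_b, bg_length = 14500, gc = gc,
                           seed = substream_seed(seed, "nineB"), id = "scf_2",
                           env_parts = sim_a$env_parts)
  list(genome = bind_rows(sim_a$genome, sim_b$genome),
       truth = bind_rows(sim_a$truth, sim_b$truth),
       queries = env_queries_from_parts(sim_a$env_parts),
       specs = c(specs_a, specs_b))
}

#' Simulated reverse-transcriptase panel
#'
#' Synthetic stand-in for an RT protein panel: one family evolved from a
#' common ancestor, with an Atlas-like and a Cer13-like sequence as a
#' recently diverged sister pair and six more distant belpaovirus-like
#' taxa, so the expected nearest neighbor of `Atlas_RT` is `Cer13_RT`.
#'
#' @param seed Integer seed.
#' @param length RT length in residues (default 300).
#' @return Tibble `id`, `seq`.
#' @export
rt_panel <- function(seed = 1, length = 300) {
  evolve <- function(aa, d, tag) {
    with_seed(substream_seed(seed, paste0("rt-", tag)), {
      chars <- strsplit(aa, "")[[1]]
      p <- 1 - exp(-d)
      hit <- runif(length(chars)) < p
      for (i in which(hit)) chars[i] <- sample(setdiff(aa20, chars[i]), 1)
      paste0(chars, collapse = "")
    })
  }
  root <- with_seed(substream_seed(seed, "rt-root"), random_aa(length))
  anc_nem <- evolve(root, 0.20, "ancnem")
  others <- c("TasV_RT", "NinV_RT", "PaoV_RT", "SuzV_RT", "BelV_RT",
              "MooV_RT")
  tibble(
    id = c("Atlas_RT", "Cer13_RT", others),
    seq = c(evolve(anc_nem, 0.05, "atlas"),
            evolve(anc_nem, 0.10, "cer13"),
            vapply(seq_along(others), function(i) {
              evolve(root, 0.45 + 0.05 * i, others[i])
            }, character(1)))
  )
}
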