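---
title: "evescreen: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{evescreen: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evescreen)
```

## What the screen decides, and from what evidence

An intact endogenous viral element (EVE) of the LTR-retroelement kind is
recognizable from four independent lines of sequence evidence: a pair of
long terminal repeats whose identity dates the integration (both copies
derive from one template at insertion, so 100% identity means recent); a
single uninterrupted Gag-Pol-Env reading frame; a reverse-transcriptase
polymerase-site motif; and an envelope whose architecture identifies its
ancestry — a single heptad-bearing glycoprotein for retroviruses, tandem
GN/GC cassettes with a class II fusion protein for phlebovirus-like
envelopes. `evescreen` computes each line of evidence explicitly and
combines them into one of four verdicts:

* `intact_EVE_phlebovirus_env` — intact LTR pair ∧ complete polyprotein ∧
  phlebovirus-like Env;
* `complete_polyprotein_other_env` — complete polyprotein, but the LTRs
  are degenerate/truncated or the Env evidence falls short;
* `incomplete` — element evidence present, coding capacity disrupted;
* `rejected` — a homology seed with no element structure behind it.

The taxonomy deliberately separates "complete polyprotein" from "intact
everything": published element tables list complete-polyprotein loci
whose LTRs are degenerate or clipped by the assembly alongside fully
intact ones, and a screen should preserve that distinction rather than
guess a single cutoff.

## Homology search

The seeding search is an exact Smith–Waterman over all six reading frames
of every contig (C++ core; score-only rolling pass, then windowed
traceback, iterated with masking so several elements on one contig are
all found). Defaults are the community's BLOSUM62 conventions: gap open
11, extend 1, where a gap of length $k$ costs $11 + (k-1)$. Raw scores
are normalized to bits, $b = (\lambda S - \ln K)/\ln 2$ with the gapped
constants $\lambda = 0.267$, $K = 0.041$, so thresholds do not depend on
the matrix. Loci are seeded at ≥ 50 bits over ≥ 80 aligned residues, and
same-strand hits within 1,000 nt merge into one locus (an envelope
cassette often aligns in pieces, and separate GN and GC queries hit
adjacent spans of one element).

E-values are *not* computed. They depend on the size of the database
searched, which makes them irreproducible outside the original search
context; bit score plus aligned length carries the same decision.

A second search iteration can use a position-specific scoring matrix
built from the first-round alignment: per-column log-odds in half-bits
against the BLOSUM62 background, with substitution-matrix pseudocounts
(the pseudocount distribution of a column is the matrix-implied
conditional distribution of its observed residues, so a single-sequence
column at high pseudocount weight recovers the substitution scores
themselves). Columns with more than 50% gaps are dropped.

When two queries hit overlapping spans of one polyprotein — common when
the queries are themselves related cassettes — the span assignment keeps
only the best-scoring hit per region (greedy by bit score, discarding
hits that overlap an accepted one by more than 30% of the shorter span).

## LTR detection

Within each locus the first and last `flank_window` nucleotides are
aligned locally (match +2, mismatch −3, gap open 5, extend 2; all
configurable). Two boundary-polishing steps follow, because the optimal
local alignment can wander a few noisy gapped columns past a repeat
boundary: terminal columns are trimmed until the outermost 20 columns
are gap-free with at most one mismatch and the terminal column is a
match, and the trimmed core is then extended outward exactly (while both
next characters are equal). Repeat identity is percent matches over
aligned columns *including* gap columns — the conservative convention of
common identity matrices — and `identity_matrix()` applies the same
convention pairwise to repeat sets.

Classification: **intact** at identity ≥ 95% and length within
[100, 1500] nt; **degenerate** below the identity threshold;
**truncated** when one short copy (≥ 40 aligned nt) abuts a contig end —
assemblies clip repeats, and the published element tables include exactly
this case; **solo** when a supplied reference repeat has exactly one
strong copy in the locus. Target-site duplications are not required for
any call. The 95% threshold brackets the identity range reported for
complete elements of this family while excluding microsatellite hits;
the [100, 1500] length window brackets the canonical 271-nt repeat.

One pipeline default deviates from the obvious choice and deserves its
rationale: the locus flank extracted before LTR search is **8,000 nt**,
not a conventional 1–2 kb. With envelope-protein queries the homology
locus sits in the 3′ third of the element (the envelope cassette begins
roughly 6 kb downstream of the 5′ LTR in the canonical 9.2-kb element),
so the flank must bridge from the hit back past the 5′ LTR; 8 kb covers
elements up to ~16 kb at the cost of a larger alignment, which the C++
core absorbs.

## Polyprotein integrity and the polymerase motif

`longest_orf()` enumerates ATG-to-stop ORFs in all six frames (ties:
forward strand, then leftmost start). *Complete* requires a start codon,
zero internal stops, ≥ 1,500 codons — the shortest credible Gag-Pol-Env
polyprotein is well above that; the canonical element encodes 2,828
residues — and coverage of ≥ 80% of the inter-LTR interior. "No introns"
is operationalized as exactly this single-ORF coverage test; no splice
modeling is attempted, because the uninterrupted ORF *is* the evidence.
When the element could not be delimited (truncated LTR), the coverage
test is waived rather than fabricated.

The polymerase-site scan looks for the first Y-X-D-[D/N] in the middle
third of the polyprotein (the Pol region in the canonical layout);
restricting the span avoids chance matches in Gag or Env, and a
full-length scan is one argument away. The fourth residue separates the
canonical `YxDD` from the `YVDN` variant that marks nematode
belpaoviruses. Polyprotein partition anchors Pol at the motif (470
residues upstream by default, the typical protease/RT spacing in this
family) and takes Env from the envelope-hit union; absent anchors leave
spans undetermined rather than guessed.

## Envelope architecture

Hydropathy is the Kyte–Doolittle sliding mean, window 19, threshold 1.6,
minimum segment 17 residues, dips shorter than 5 residues merged — the
canonical settings for TM prediction from first principles; the source
analyses never name their predictor, so these standard values are a
declared substitute, all configurable. Sequons are N-X-[S/T] with X ≠ P.
The tandem call requires a GC-query hit occupying the C-terminal portion
of the Env, a distinct upstream GN-like region (own TM or GN hit), and
exactly one C-terminal TM in the GC region; proteolytic cleavage sites
are approximated by the region boundaries adjacent to TM segments, since
the discriminating evidence is layout, not cleavage chemistry. The
retrovirus-like alternative requires a single TM with a heptad-bearing
ectodomain (a/d-position hydrophobicity over 28-residue windows, best
phase ≥ 0.8). Signal peptides are out of scope — the polyprotein
N-terminus plays no part in the classification.

## Phylogeny

Progressive alignment: 3-mer guide distances, average-linkage guide
tree, profile-profile merging under the same scoring machinery as the
search; at each merge the two profiles are ordered by their smallest
member id, so the alignment is independent of input order. Distances are
Poisson-corrected, $d = -\ln(1-p)$, with gapped columns excluded
pairwise (not listwise — RT fragments differ in coverage) and saturated
pairs capped at 10 substitutions/site. Trees come from classic neighbor
joining (`ape`), with negative branch-length estimates clamped to zero
and reported. NJ rather than maximum likelihood is a deliberate choice:
the claims this package tests are nearest-neighbor relations, which are
robust to method at these divergences; an ML backend would be an
extension, not a correction. Nearest neighbors minimize patristic
distance, ties broken alphabetically and reported.

## The synthetic-data generator

`eve_spec()`/`assemble_eve()`/`plant_eves()` build genomes in which every
quantity the screen reports has a planted true value. An element is
`LTR5 — linker — ORF — linker — LTR3`, where the 3′ LTR derives from the
5′ copy by per-site substitution (no indels: the reported quantity is
percent identity, and substitutions exercise the identity machinery;
indel support is a flagged extension). Defaults are the canonical intact
anatomy: 271-nt LTRs, a 2,830-codon ORF in cassette order Gag | Pol
(motif mid-Pol) | Env (GN + GC), two planted 23-residue TM-like
stretches drawn from {L,I,V,F,A} — longer than the 19-residue caller
window by design — a single GC sequon, and a planted cysteine census.
Disruption labels generate the decoy classes: a mid-ORF stop, a
single-nucleotide frameshift, heavy LTR degeneration (divergence ≥
0.15), 3′-LTR truncation at a contig end, and solo LTRs.

Three generator properties make "exact recovery" a well-posed test
rather than a coin flip:

* **Exact repeat termini.** Substitutions are planted in the repeat
  interior, leaving 20 nt at each end exact (with canonical TG…CA
  dinucleotides). Real LTR termini are the most constrained part of the
  repeat; operationally, exact termini make the planted boundary — and
  therefore the true length and identity — unambiguous.
* **Boundary sharpening.** The six background bases flanking each
  planted copy are forced to mismatch their alignment-extension
  counterparts inside the element, so the planted pair is the unique
  maximal local alignment.
* **Stop-padded linkers.** A 12-nt pad with stop codons in all three
  frames (and no ATG) sits between each linker and the ORF, so the
  longest ORF is exactly the planted one.

Ground truth records *realized* quantities — LTR identity is computed
from the emitted pair, not the nominal divergence — and the expected
verdict derives from the realized identity, so an element planted near
the 95% threshold is judged by what was actually emitted.

One shared seed drives everything through labelled substreams
(`substream_seed()` hashes a tag into a 31-bit stream seed with overflow
-safe modular arithmetic), so a whole benchmark reproduces from one
integer and re-ordering independent components never changes their
output.

**What the benchmarks do not show.** The background is i.i.d. nucleotide
sequence at a fixed GC fraction; real assemblies carry host genes, repeat
landscapes, segmental duplications and N-runs, any of which can add
homology seeds or repeat hits that these benchmarks never present. The
planted envelope cassettes are exact matches to the queries, so recall
on the benchmark (100% at default thresholds) is an upper bound;
detecting a diverged envelope at 20–25% identity is governed by the
bit-score threshold, not demonstrated here. Verdict *accuracy* on
planted disruptions, boundary *exactness*, and the null behaviour on
element-free backgrounds are what the benchmarks establish.

## Study designs bundled with the package

* `benchmark_genome(seed)` — the default recovery benchmark: two
  contigs, 10 intact elements at divergences 0 (×4), 0.02 (×3), 0.05
  (×3) and 10 decoys, two per disruption class, with truncated elements
  at contig ends. Elements share one envelope cassette family (whose GN
  and GC proteins are the screen queries, mirroring a screen seeded by
  known envelope sequences) and draw Gag/Pol per element.
* `atlas_like_locus(seed)` — a synthetic stand-in, *not* the public
  accession, built to the published intact-element signature: 9,204-nt
  element, identical 271-nt LTRs, 2,828-residue polyprotein, `YVDN`,
  envelope cassettes at polyprotein 1909–2329 (GN-like) and 2330–2828
  (GC-like), one C-terminal TM, a single sequon at GC position 414, 30
  cysteines in GC 1–443. The test it supports is that the screen reads
  this whole signature back from sequence alone.
* `nine_eve_assembly(seed)` — a multi-contig assembly emulating the
  published nine-element composition (seven intact-LTR, one
  degenerate-LTR, one truncated-LTR complete-polyprotein elements, plus
  disrupted decoys).
* `rt_panel(seed)` — a simulated RT protein family in which an
  Atlas-like and a Cer13-like sequence are a recently diverged sister
  pair among six distant relatives; the expected nearest neighbor is the
  sister taxon by construction, and the test exercises the full
  alignment → distance → NJ → patristic chain.

Problem sizes were chosen to exercise every code path at desk scale: the
default benchmark genome is ~250 kb across two contigs and screens in
well under a minute; the acceptance script re-runs the benchmark, the
reference-anatomy locus, the nine-element assembly and the RT panel in a
few minutes end to end.

## Numerical and degenerate-input behaviour

Alignment scores are exact dynamic programming (no heuristics); the
score-only pass and the windowed traceback agree by construction, and
the window doubles until the reconstructed path reproduces the optimal
score. Empty sequences score 0 with an empty alignment (not an error).
Ambiguity codes other than N are rejected on input rather than silently
translated, because stop-codon integrity checks must be unambiguous;
N-containing codons translate to X. Ties are broken deterministically
everywhere (alignment traceback preference, ORF strand/position, NJ via
`ape`'s fixed order, alphabetical nearest-neighbor ties), so identical
inputs give byte-identical TSV/GFF3/Newick outputs. Coordinates are
1-based inclusive throughout (GenBank/GFF3 convention) so outputs
interleave with public annotations.

## Known limitations

* Genome-wide *de novo* LTR discovery without a homology seed is out of
  scope (no k-mer seeding à la LTRharvest); a solo LTR with no coding
  sequence is invisible to this screen, by design.
* The substitution-only divergence model means the identity machinery is
  never exercised against indel-bearing repeats from the generator
  (though the aligner itself handles gaps).
* Profile-HMM domain annotation (protease/integrase, RVT_1) is replaced
  by motif anchoring; partition boundaries are approximate (±30 residues
  on planted data).
* Maximum-likelihood trees, bootstrap support and tree visualization are
  not provided.
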