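# evescreen

Screening genome assemblies for intact endogenous viral elements (EVEs)
with phlebovirus-like envelope glycoproteins.

## The problem

Endogenous viral elements are viral genomes that integrated into a host
germline and are inherited vertically. Most decay quickly, but an element
that retains *all* of its parts — identical long terminal repeats (LTRs),
one uninterrupted Gag-Pol-Env polyprotein, a recognizable reverse
transcriptase (RT), and a plausible envelope — is a recently active,
potentially functional virus hiding in a host assembly. In nematodes, a
family of such elements (belpaoviruses) carries something unexpected in
place of a retroviral envelope: tandem G<sub>N</sub>/G<sub>C</sub>
glycoprotein cassettes of the kind phleboviruses use, with
G<sub>C</sub> a class II membrane fusion protein.

`evescreen` implements the complete chain of evidence needed to make that
call from sequence alone, for anyone screening an assembly with envelope
protein queries:

1. **Homology seeding** — exact six-frame Smith–Waterman search of every
   contig with protein queries (affine gaps, BLOSUM62, Karlin–Altschul
   bit scores: `bits = (λ·S − ln K)/ln 2`), plus a second-iteration
   position-specific scoring matrix (PSSM, half-bit log-odds with
   substitution-matrix pseudocounts) built from first-round hits.
   E-values are deliberately not computed — they depend on database size —
   so loci are seeded at ≥ 50 bits over ≥ 80 aligned residues.
2. **LTR detection** — best local alignment between the two ends of each
   seeded locus, with boundary polishing; pairs classified
   intact (identity ≥ 95%) / degenerate / truncated (clipped at a contig
   end) / solo / none; identity is percent matches over aligned columns,
   gap columns included.
3. **Polyprotein integrity** — longest ATG-to-stop ORF over six frames;
   *complete* means: start codon, zero internal stops, ≥ 1500 codons, and
   ≥ 80% coverage of the inter-LTR interior (the operational reading of
   "no introns").
4. **RT motif** — first Y-X-D-[D/N] in the Pol third: `YxDD` is the
   canonical polymerase site, `YVDN` the nematode belpaovirus variant.
5. **Env architecture** — Kyte–Doolittle hydropathy (window 19, threshold
   1.6), transmembrane (TM) segment calls, N-X-[S/T] (X ≠ P) sequon scan
   and cysteine census decide between tandem phlebovirus-like
   G<sub>N</sub>+G<sub>C</sub> cassettes and a retrovirus-like single
   glycoprotein.
6. **Phylogeny** — progressive alignment (k-mer guide tree,
   profile-profile merging), Poisson-corrected distances
   d = −ln(1 − p), and neighbor joining, to ask which known element is a
   candidate's nearest RT neighbor.

A fully seeded synthetic-genome generator plants elements with ground
truth (and decoys: solo LTRs, degenerate/truncated LTRs, stop- and
frameshift-disrupted ORFs), so the entire screen is testable offline.

## Worked example

```r
library(evescreen)

# a synthetic benchmark: 10 intact elements (271-nt LTRs at divergence
# 0/0.02/0.05) and 10 decoys, planted across two contigs with truth
bench <- benchmark_genome(seed = 1)
scr   <- run_screen(bench$genome, bench$queries)
glance(scr)
#> # A tibble: 1 × 6
#>   n_hits n_loci n_intact n_complete_other n_incomplete n_rejected
#>    <int>  <int>    <int>            <int>        <int>      <int>
#> 1     36     18       10                4            4          0

evaluate_screen(scr, bench$truth) |> dplyr::count(expected, match)
# 20 of 20 verdicts equal the planted truth; solo-LTR decoys are
# correctly invisible to a homology-seeded screen

# single-locus mode on a synthetic locus with the canonical intact
# anatomy (9,204-nt element, 271-nt identical LTRs, 2,828-aa polyprotein)
al   <- atlas_like_locus(seed = 1)
cand <- validate_locus(al$genome, al$queries)
cand[, c("element_length_bp", "ltr_length_bp", "ltr_identity_pct",
         "polyprotein_length_aa", "rt_motif", "env_class", "verdict")]
#>   element_length_bp ltr_length_bp ltr_identity_pct polyprotein_length_aa
#> 1              9204           271              100                  2828
#>   rt_motif              env_class                    verdict
#> 1     YVDN phlebovirus_like_GN_GC intact_EVE_phlebovirus_env
```

The numbers read: the locus is delimited by a 271-bp repeat pair at 100%
identity (recent integration), the 9,204-bp element encodes one
uninterrupted 2,828-residue polyprotein whose polymerase site carries the
belpaovirus `YVDN` variant, and the envelope shows the tandem
G<sub>N</sub>/G<sub>C</sub> layout — the full verdict
`intact_EVE_phlebovirus_env`.

Results flow into the usual surfaces: `tidy()` / `glance()` on the screen
object, `autoplot()` for an element map, `plot_hydropathy()` for TM
profiles, `write_report_table()` (TSV) and `write_gff3()` for
interchange. `exec/evescreen` exposes the same stages as shell
subcommands (`simulate | search | ltr | orf | env | phylo | screen |
validate`).

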