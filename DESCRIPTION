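Package: evescreen
Title: Screening Genome Assemblies for Intact Endogenous Viral Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening pipeline for endogenous viral elements (EVEs) of the
    LTR-retroelement kind. Given a genome assembly and envelope-protein
    queries, evescreen seeds candidate loci by translated Smith-Waterman
    homology search (optionally with a position-specific scoring matrix),
    detects and classifies the long terminal repeat (LTR) pair that delimits
    each element, verifies Gag-Pol-Env polyprotein integrity, classifies the
    reverse-transcriptase polymerase-site motif (YXDD versus the nematode
    belpaovirus YVDN variant), annotates envelope architecture
    (phlebovirus-like tandem GN/GC cassettes versus a retrovirus-like
    glycoprotein) from hydropathy, sequon and cysteine evidence, and places
    candidate reverse transcriptases on a neighbor-joining phylogeny. A
    seeded synthetic-genome generator plants elements and decoys with ground
    truth so the whole screen is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
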