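Package: snvspace
Title: Evolutionary Analysis of Drug-Resistance Missense Mutations in Kinase Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether missense drug-resistance mutations in kinase
    drug targets (EGFR, ALK, Abl1) correspond to residue variations observable
    among evolutionarily related sequences. Enumerates the single-nucleotide-
    variant (SNV) accessible amino-acid space of a coding domain under the
    standard genetic code, maps mutations onto a multiple sequence alignment
    with a designated reference row and classifies them as occurred or novel,
    computes ordered conditional co-occurrence matrices for compound mutations,
    scores mutations with Grantham biochemical distances, CDD-style PSSM
    log-odds and ConSurf-style conservation values, and quantifies enrichment
    of resistance mutations inside the observed portion of SNV space with an
    exact binomial tail test. Includes a synthetic alignment and coding
    sequence generator with planted column frequencies and pairwise couplings
    so every analysis stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
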