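---
title: "Evolutionary analysis of kinase drug-resistance mutations with snvspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary analysis of kinase drug-resistance mutations with snvspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvspace)
```

## The question the package answers

Targeted kinase inhibitors (imatinib against Abl1, erlotinib/gefitinib
against EGFR, crizotinib against ALK) fail when the tumour acquires missense
*resistance mutations* in the drug-target kinase domain. All of the clinically
catalogued resistance mutations arise from single nucleotide variants (SNVs).
If such mutations were constrained only by the requirement that they confer
resistance, the residues they introduce should be scattered uniformly over
the SNV-accessible amino-acid space of each codon. If instead the mutant
protein must remain a functional kinase, purifying selection should confine
resistance mutations to residue states that evolution has already explored —
states observable at the homologous position of related proteins.

`snvspace` implements the full analysis chain needed to test this: codon-level
enumeration of the possible SNV space, occurrence classification of mutations
against a multiple sequence alignment (MSA), conditional co-occurrence of
compound (double) mutations, biochemical and conservation scoring, and an
exact binomial enrichment statistic.

## The model, stage by stage

### Codon SNV space

A codon has nine single-base substitutions. `missense_neighbors()` translates
each under the standard genetic code and keeps the *distinct* amino acids,
discarding synonymous outcomes and substitutions that create a stop codon.
Distinctness is counted at the protein level: for the serine codon AGC, eight
of the nine substitutions are missense at the nucleotide level but they
collapse to six residues, `{R, G, C, N, T, I}`. Stop-creating substitutions
are excluded because the analysis concerns missense space; including them
would inflate the per-codon mean well above the 5.8–5.9 replacements per
codon that natural coding sequences show. `count_possible_missense()` sums
neighbourhood sizes over a `coding_domain`, giving the "possible" SNV count
for a kinase domain. Only the standard genetic code is supported, and only
single-nucleotide events (no codon-usage weighting, no transition/transversion
asymmetry, no dinucleotide changes) — the SNV model is deliberately the
simplest one consistent with how the mutations are catalogued.

### Occurrence in an alignment

`build_profile()` ingests an aligned FASTA family with one designated,
gapless-in-coordinates reference row and a `reference_offset` that anchors the
row in full-protein numbering (mutations are always written in full-protein
coordinates, e.g. T315I of Abl1 even though the kinase domain starts at
residue 235). Each reference residue maps to exactly one alignment column;
reference gap columns are unmappable.

A mutation is **occurred** when its mutant residue appears at the mapped
column in at least one row, otherwise **novel**. Two conventions matter and
are fixed throughout:

* The denominator is always the total number of rows, reference included.
  Rows with gaps or ambiguity codes (X, B, Z, J, U, O) stay in the
  denominator and can never match a mutant residue. This convention is what
  makes the printed fractions 87/276, 146/276 and 51/276 internally
  consistent.
* `report_percent()` truncates toward zero: 87/276 = 31.5% prints as "31%",
  and fractions below 1% keep one (truncated) decimal, e.g. "0.3%". A
  rounding convention would print "32%" and is therefore wrong for this
  analysis.

`observed_spectrum()` combines both stages: per domain position it intersects
the codon's reachable set with the residues present in the column, yielding
the possible/observed SNV spectrum of the domain. An optional
`min_confidence` argument can mask alignment columns below a GUIDANCE-style
confidence threshold; it is off by default because occurrence counting is
defined over the full alignment.

### Compound mutations

For two resistance mutations A and B, `conditional_cooccurrence()` computes
the directional frequency P(B | A): among rows carrying A's mutant residue,
the fraction also carrying B's. The matrix over all ordered pairs
(`compound_matrix()`) is generally asymmetric — P(B | A) and P(A | B) share
the joint count but divide by different marginals. Cells are binned on the
percentage scale as `< 10` (white), `[10, 19)` (yellow), `[19, 50]` (orange)
and `> 50` (red); the two middle bins share the boundary value 19 in their
conventional labels, and the overlap is resolved in favour of the higher bin.
Two derived scans are provided:

* `find_novel_compounds()`: pairs never seen together in any row although
  each single variant occurs — candidate compound mutations with no
  evolutionary precedent.
* `find_obligate_pairs()`: pairs with conditional frequency 1 in *both*
  directions and joint count at least 1. "Always observed together" is
  directionally ambiguous; the bidirectional reading is the strictest and is
  the default, with `bidirectional = FALSE` available for the weaker one.

Same-position mutation pairs (e.g. Y253F and Y253H) cannot be conditioned on
each other; they are skipped with a warning rather than failing the whole
matrix. No phylogenetic correction is applied: co-occurrence may reflect
shared ancestry rather than co-selection, and the package intentionally does
not try to separate the two.

### Biochemical and conservation scoring

`grantham_distance()` returns the canonical integer Grantham matrix, the
empirical biochemical distance built from side-chain composition, polarity
and volume (conservative Ile→Leu = 5; radical Cys→Phe = 205; mean over the
190 pairs = 100, the Phe/His distance). The published integer table is the
source of truth; `grantham_from_properties()` re-derives distances from the
property formula with the scale factor normalised so the mean pair distance
is 100. The formula reproduces the table within about one unit for 189 of
190 pairs; the Trp–Asp entry is printed as 181 in the canonical table while
the formula gives about 191, an internal inconsistency of the original table
that the package documents rather than silently repairs.

`read_pssm()` ingests the NCBI ASCII position-specific scoring matrix layout
(log2 odds per residue per position, optionally followed by observed
frequency percentages). `pssm_delta()` classifies a mutation as
`mutant_more_conserved`, `similar` or `mutant_less_conserved` by comparing
the mutant's and wild type's scores; when frequency data are present and the
mutant's observed frequency is 0 the classification is `not_present`,
overriding the score comparison. "Similar" means exact score equality by
default because CDD exports integer scores; `similar_tol` relaxes this.

`read_conservation()` ingests ConSurf-style per-residue scores (lower /
negative = more conserved); the scores are never recomputed here — rate
estimation belongs to the upstream server. `median_conservation()` collapses
mutations to unique positions first (several SNVs of one residue count its
score once), then takes the median. `median_grantham()` by contrast counts
every mutation once by default, because the per-residue rule is documented
only for conservation scores; `per_residue = TRUE` switches conventions.
Medians of even-length sets use the arithmetic midpoint.

### The enrichment statistic

Let `p` be the fraction of all possible missense SNVs in the studied domains
that are observed in the alignments (pooled over genes), and let `k` of `n`
resistance mutations be observed. Under the null hypothesis that all
possible missense SNVs are equally probable, the number of
alignment-observed resistance mutations is Binomial(n, p), and
`binomial_tail()` returns the exact upper tail

$$P(X \ge k) \;=\; \sum_{j=k}^{n} \binom{n}{j} p^j (1-p)^{n-j},$$

summed in log space. With the pooled study counts (p = 3382/4676, k = 52,
n = 55) the tail is of order 10⁻⁵ — resistance mutations are strongly
confined to the evolutionarily observed part of SNV space. The published
analysis reports a value of the same order whose exact construction is not
stated; the pooled binomial reading implemented here (and its per-gene
stratified variant, `stratified = TRUE`, which multiplies per-gene tails)
reproduces the order of magnitude but not the printed mantissa, so the
package treats this quantity as an order-of-magnitude result. Exact
summation is used rather than a normal approximation because `n` is small;
no multiple-testing correction is applied because only one test is made.

## The synthetic-data generator

Real homolog families cannot be redistributed with the package, and the 2013
search/filter/alignment tool chain (DELTA-BLAST, skipredundant, MAFFT,
GUIDANCE) is upstream of its scope — the MSA is an input. `simulate_msa()`
therefore generates families with *known* ground truth:

* rows are exchangeable and columns independent — exactly the statistical
  structure the occurrence analysis assumes — except for explicitly planted
  structure;
* each non-reference cell carries the reference residue with probability
  1 − ε (default background rate ε = 0.02 in the examples, a few percent of
  scattered substitutions, comparable to a conserved-domain family trimmed at
  95% identity);
* *supports* plant a variant residue at a stated position with a target
  frequency; *couplings* plant a coupled haplotype (residue a at position i
  AND residue b at position j) in a stated fraction of rows. The coupling
  fraction is the **joint** share of rows, so it can never exceed either
  marginal target; the implied conditional frequency is
  `fraction / marginal(first)`. Planting assigns whole rows, and the
  background draw at planted columns excludes the planted residues, so the
  ground-truth table records *exact* realised counts, not expectations;
* gaps can be injected per cell (`gap_rate`, default 0) on non-planted cells
  to exercise the denominator rules;
* the same spec (including its seed) yields byte-identical FASTA and
  ground-truth TSV output.

What passing tests on synthetic families demonstrate: coordinate mapping,
counting conventions, conditional arithmetic and recovery of planted
frequencies within binomial tolerance. What they cannot demonstrate:
behaviour under phylogenetic correlation between rows (real families are
tree-structured, not exchangeable), alignment error, or the composition of
real homolog sets — conclusions about real kinase families still depend on
the quality of the input MSA. `simulate_cds()` complements the generator
with a coding sequence drawn uniformly over synonymous codons, so codon-level
and alignment-level stages can be tested jointly.

## Numerical and design choices

* Codons are uppercased, RNA U is accepted as T, and only `{A,C,G,T}` pass
  validation; a mutation token whose stated wild type conflicts with the
  reference (or the CDS translation) raises a validation error naming the
  expected and found residues rather than guessing which input is wrong.
* Mutation tokens are `<AA><position><AA>` with 1-based full-protein
  positions; compound tokens `A/B` preserve order because the conditional
  analysis is directional. Identity "mutations" (T315T) are rejected.
* The test suite runs at deliberately desk-sized scales — families of
  60–500 rows, reference proteins of 9–40 residues, 20 generator seeds for
  the recovery properties, 300-codon simulated domains — chosen so that the
  binomial 3σ tolerances are meaningful while the whole suite stays fast.
* Undefined conditionals (condition never observed) are `NA`, never 0: a
  variant absent from the family carries no information about what co-occurs
  with it.
* All tabular output is headered, tab-delimited, UTF-8, `.`-decimal
  (`write_tsv()`); compound matrices export row-major over the input
  mutation order.

## Known limitations

* Occurrence is a binary per-column criterion ("at least one homologous
  sequence"); it does not weight by how many rows carry the variant, nor by
  sequence similarity to the reference.
* Compound co-occurrence counts alignment rows, not independent evolutionary
  events; shared ancestry inflates conditional frequencies.
* The enrichment statistic assumes all possible missense SNVs equally
  probable and pools genes into one background; both simplifications are
  inherited from the analysis the package reimplements, and the stratified
  variant is provided for sensitivity analysis.
* PSSM and conservation scores are ingested, never computed: the package has
  no homology-search or rate-estimation machinery by design.
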