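---
title: "Methods: comparative protein evolution, methylation and divergence in chalcid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative protein evolution, methylation and divergence in chalcid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chalcidEvo)
```

This vignette documents the statistical models behind `chalcidEvo`,
the parameter choices that matter, what the synthetic-data generators
do and do not emulate, and the numerical conventions adopted where a
published procedure leaves details open.

## Place ranking of ortholog branch lengths

The unit of analysis is a set of single-copy orthologs, each with a
gene tree constrained to one rooted species topology but carrying its
own branch lengths. Two anchor nodes are resolved in every gene tree
as most recent common ancestors of leaf sets (never by node labels): a
clade ancestor (here, Chalcidoidea) and a deeper in-group ancestor
(Hymenoptera minus the rooting sawfly). For each clade member the
species-to-clade-root path length measures amino-acid change since the
clade ancestor; the clade-root-to-order-root path is the "base"
distance, a per-protein proxy for its baseline rate.

Within each ortholog, clade members are ranked by descending distance
(place 1 = longest branch). Under the null that all `k` species are
equally likely to carry the longest branch, each species' first-place
count is Binomial(`n`, `1/k`) with expectation `n/k`
(`expectedPlaceCount()`); observed place counts are tested by
chi-squared goodness of fit and followed up with all-pairs
continuity-corrected 2×2 tests (`pairwisePosthoc()`). The Yates 2×2 on
"first place vs not" is the default pairwise construction because it
reproduces published comparisons of this form at printed precision.

Rank-discrepancy scoring orients ranks so that rank 1 is the shortest
branch; the score `comparison − base` is then positive for proteins
evolving faster in the focal lineage than their baseline predicts
(base rank 10 with median within-clade rank 1000 scores +990). To
prevent baseline-rate categories dominating, proteins are binned by
base rank into groups of 100 and the most positive and most negative
10% are selected per bin.

Conventions where real-valued branch lengths leave room:

* ties in place or rank are broken deterministically by species-name
  or protein-id order and the affected orthologs/bins are flagged;
* the median of an even number of ranks is the mean of the middle two,
  and half-integer scores are rounded half away from zero;
* orthologs with a zero base distance are excluded from normalized
  analyses with a warning rather than producing infinities;
* the final base-rank bin carries the remainder (1311 = 13×100 + 11),
  and per-bin selection is `round(fraction × occupancy)` with a floor
  of 1 so small bins still contribute.

## Tajima's relative rate test

For an in-group pair (A, B) polarized by an out-group O, `mA` counts
alignment columns where A differs while B and O agree, and vice versa.
Under rate equality `E[mA] = E[mB]`, and
`chi2 = (mA − mB)²/(mA + mB)` is asymptotically chi-squared on 1 df.
Columns containing a gap, `X` or `*` in any sequence are skipped — a
conservative choice where the published procedure is silent. With
`mA + mB = 0` the test is undefined and reported as such rather than
silently `p = 1`.

The masking filter (`maskAlignment()`) is a documented stand-in for
external divergence-masking tools: it removes every gap-containing
column plus all columns of any width-10 sliding window whose mean
pairwise identity falls below 0.5 (both configurable). It is not
byte-compatible with Gblocks; pre-masked alignments can be supplied
instead. Masking can only remove columns, so it never increases the
counts. Per-gene significance summaries apply Benjamini–Hochberg at
0.05 by default (raw-α mode available), since published per-gene
counts of this kind rarely name their correction.

## Count statistics

Goodness of fit and 2×2 tests delegate to the standard Pearson
machinery; term overrepresentation is the hypergeometric upper tail
per term with BH adjustment, with the background defaulting to all
genes carrying at least one annotation term. All p-values live in
(0, 1]; a zero 2×2 margin is reported as undefined.

## Gene-family categories

From an OrthoMCL-style groups file plus explicit per-species gene
universes: a family in every species with exactly one gene each is
single-copy core; in every species with a duplication somewhere,
variable-copy core; in at least two but not all species, dispensable;
a cluster of ≥2 genes from one species, species-specific; an
unclustered gene, a singleton. A "missing family" requires a sole
absentee — families absent from two or more species count for no one.
The family annotation-term rule keeps a term carried by at least 40%
of members (inclusive boundary: 4 of 10 qualifies). Making the gene
universes an explicit input resolves the otherwise ambiguous singleton
denominator (all annotated genes vs genes entering clustering).

## Gene models, methylation and divergence

GFF3 gene models stay 1-based inclusive throughout; genes with
multiple mRNAs are represented by the longest-CDS isoform so per-gene
summaries see one value per gene. Intron totals are the gaps between
consecutive exons; length comparisons use one-way ANOVA on raw totals
(no transform by default) with Tukey HSD follow-up.

Dinucleotide depletion uses `O/E = N_XY × L / (N_X × N_Y)` with
overlapping windows; windows containing `N` are skipped with `L`
reduced accordingly. Using `L` rather than `L − 1` shifts values by
`L/(L−1)` — negligible for real CDS and fixed across tests. CpG O/E
is reverse-complement invariant, and GpC O/E serves as the
no-methylation control.

Gene-body fractional methylation is read-weighted
(`Σ meth / Σ total` over covered CpG sites in the gene span), the
standard estimator; a per-site-mean mode is available. A gene is
called methylated iff its fraction strictly exceeds 0.01, with at
least 3 covered sites required for any call (configurable; the
published site filter is unstated). Positional profiles average
per-feature fractions over the first and last four exons and introns
in transcript orientation; genes with fewer features contribute only
to the slots they have. Cross-species conservation labels each
complete status tuple as conserved (all methylated / all
unmethylated), focal-specific gain or loss, or "other"; orthologs with
missing data are excluded and counted, so the labels partition the
total. Ortholog methylation correlations are product-moment on
`log10(fraction + 1e-4)`; the floor sits two orders below the call
threshold and is configurable.

Coding divergence uses Nei–Gojobori (1986) site counting — each codon
position contributes one site split by the fraction of its non-stop
single-nucleotide changes that are synonymous, keeping `N + S = 3 ×`
codons — with multi-difference codons averaged over stop-avoiding
mutational pathways and Jukes–Cantor correction. The estimator choice
is a documented default (raw `pN`/`pS` are also reported), since
pipelines of this kind often leave it unnamed. Variant classification
uses region precedence coding > UTR > intron > intergenic; coding
SNPs are recomputed through the genetic code
(silent/missense/nonsense) and CDS indels are frameshifts iff their
length difference is not a multiple of 3. Top-divergence selection
(missense per amino-acid site) includes all genes tied at the cutoff.

## The synthetic-data generators

Each generator draws from a private RNG stream derived from the master
seed plus the generator name, so outputs are byte-stable and adding a
generator never perturbs another. Defaults describe the study
conditions the analyses assume; they are fixed, not tuned.

* **Gene trees.** Branch `e` of ortholog `g` has length
  `base_e × r_g × u_ge × m_e`: `r_g` a mean-1 gamma ortholog rate
  (shape 2 — rate heterogeneity across proteins of the magnitude seen
  in comparative data), `u_ge` i.i.d. mean-1 gamma branch noise
  (shape 5, milder than the ortholog effect), and `m_e` a lineage
  multiplier on a terminal branch. The branch-noise term is required:
  with a purely ortholog-level rate, every tree would be a rescaled
  species tree and within-ortholog ranking would be degenerate. With
  both shapes infinite and multipliers 1 the species tree is recovered
  exactly. The default eight-taxon ultrametric phylogeny has a
  ladder-shaped four-species clade, whose members are therefore not
  exactly exchangeable under branch noise; exact uniformity of
  first-place counts is checked on a symmetric balanced four-taxon
  phylogeny where exchangeability holds by construction.
* **Triple alignments.** Poisson-style equal exchangeability over the
  20 residues: each column receives at most one event, on the A-only,
  B-only, O-only or shared internal branch, with per-site
  probabilities (defaults A = B = 0.02, O = 0.04, internal = 0.02 at
  length 500 — expected counts of 10 per in-group branch, a regime
  where the exact size of the nominal-0.05 test is 0.0497). The
  planted counts are recorded, and column counting recovers them
  exactly.
* **Methylome.** Two latent gene classes (37.4% methylated) with true
  gene-body fractions 0.9 and 0.001; CpG depletion mutates each CpG's
  C to T with class probability 0.6 / 0, creating the bimodal CpG O/E
  structure that motivates O/E-based methylation prediction, while
  GpC stays unimodal. Per-CpG read totals are Poisson(20) with
  binomial methylated counts; an optional geometric 5′ decay plants a
  positional gradient. Planted ORFs are strand-aware, so spliced CDS
  extraction yields stop-free frames (CpG depletion may introduce
  stops, as deamination does in real genomes).
* **Cluster tables** reproduce requested per-category counts exactly,
  with per-species gene universes including unclustered singletons.
* **Coding pairs** plant `round(p × sites)` synonymous and
  nonsynonymous single-nucleotide differences at distinct codons,
  `p = ¾(1 − e^{−4d/3})`, so Nei–Gojobori estimation recovers the
  targets (defaults dS 0.013, dN 0.0075) within sampling error.

What the generators do **not** emulate: assembly and annotation error,
alignment uncertainty and indel placement, substitution-model
heterogeneity (no GTR/ML branch estimation — the ranking and counting
procedures consume branch lengths and columns, not likelihoods),
linked sites, bisulfite conversion error (an ε hook exists but
defaults to 0), and read-level sequencing noise. Passing closed-loop
tests therefore demonstrates correctness of the downstream statistics
under their own assumptions, not robustness of upstream inference on
real data.

## Problem sizes and tolerances in the test suite

The suite exercises: 2000-ortholog place-ranking closed loops with
planted multipliers 1.5/2/4 (first-place fraction above 1/k and
monotone in the multiplier); 2000 null triple alignments of length 500
for the type-I error of the relative rate test (binomial CI around
0.05); 300-gene bimodal methylomes at coverage 20 (status recovery
≥ 95%); 10^5-codon coding pairs at dS targets 0.013 and 0.05
(recovery within two standard errors); and oracle-equivalence suites
of 100+ random instances each for place sorting, bin selection,
goodness-of-fit (multinomial Monte Carlo) and per-codon-pair pathway
enumeration. Fixed reference arithmetic — 1311/4 = 327.75 rendered
328, the +990 worked score, the p = 0.6263 continuity-corrected 2×2 —
is asserted at printed precision.

## Known limitations

* Topology is fixed: gene-tree discordance, paralogy and horizontal
  transfer are out of scope; trees failing the topology check are
  rejected, not reconciled.
* The masking filter approximates, but does not reproduce, Gblocks.
* Nei–Gojobori with Jukes–Cantor underestimates divergence under
  strong transition/transversion bias or codon-usage skew; for the
  near-intraspecific divergences targeted here the bias is small.
* Variant classification assumes a correct reference and annotation;
  overlapping genes resolve by region precedence, not by transcript
  quantification.
* The exchangeability caveat above means first-place null calibration
  on an asymmetric clade is approximate; the package tests calibration
  where it holds exactly and recovery where it does not.
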