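---
title: "Methods: inferring and placing ancient whole-genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring and placing ancient whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdinfer)
```

# Overview

`wgdinfer` infers ancient whole-genome duplications (WGDs) from
transcriptome-scale data using three lines of evidence — gene-age (Ks)
distributions, ortholog divergence, and gene-tree sorting (MAPS) — and
combines them under explicit total-evidence rules. This vignette
documents the statistical model behind each stage, the default
parameters, and the reasoning behind the less obvious methodological
choices.

# Gene ages from synonymous divergence

## Duplicate pairs and families

Paralog pairs come from an all-vs-all protein similarity search in
tabular 12-column format (`readBlastTab()`). `filterDuplicatePairs()`
keeps, for each unordered gene pair, the single best hit (highest
percent identity, ties broken by alignment length), drops self hits,
and applies minimum identity and alignment-length thresholds.
`singleLinkageFamilies()` then clusters genes into families as the
connected components of the pair graph — single linkage is deliberate:
any retained hit links two genes into the same family, which matches
how duplicate clusters are conventionally delimited for age
distributions.

## NG86 synonymous divergence

`estimateKsPair()` implements the Nei–Gojobori (1986) method directly:
synonymous and nonsynonymous sites are counted per codon by enumerating
all single-nucleotide changes under the standard genetic code;
differences between codons are averaged over all orderings of the
mutational path, excluding paths that pass through stop codons (when
every path hits a stop, all paths are used as a fallback so the codon
still contributes). The proportions are corrected with the
Jukes–Cantor formula `Ks = -3/4 · log(1 - 4 pS / 3)`. Pairs at or
beyond the saturation point (`pS ≥ 3/4`) raise a typed error and are
reported as `NA` by the vectorised `ksMatrix()`. A deliberately simple,
dependency-free NG86 implementation was chosen over heavier
maximum-likelihood codon machinery: at the divergence depths where Ks
distributions are informative (Ks ≤ 2, see below) the two approaches
agree well, and the counting method is fast enough to date millions of
pairs and simple enough to verify against an independent
site-enumeration oracle in the test suite.

## Node ages, not pair ages

Large families contribute quadratically many pairs, which would let a
single expanded family masquerade as a WGD peak. `nodeKsFromTree()`
therefore assigns one age per *duplication node* of each family tree:
the median of the pairwise Ks values across that node. The age
distribution analysed downstream (`AgeDistribution`) is the collection
of node medians, so every duplication event counts once regardless of
how many descendant pairs it left.

# Peak detection

## The null model

Under steady duplication and loss, surviving duplicate ages are
approximately exponential. Within the analysis window the null is a
truncated exponential; `fitNull()` estimates the decay rate by maximum
likelihood. The default window is `(0.01, 2]`: the lower bound excludes
the pile-up of alleles, splice variants and near-identical recent
copies; the upper bound is the saturation-motivated Ks ≤ 2 rule.
`detectWgd()` also supports a wider `(0.01, 5]` window for visualising
deep structure, but peaks with median Ks > 2 are only ever reported as
`needs-corroboration` — saturation and alignment noise make their
position unreliable, so they require support from an independent line
of evidence before being treated as WGDs.

## The K-S gate

`ksGoodnessOfFit()` performs a two-sample Kolmogorov–Smirnov test of
the observed in-window ages against a large sample (default 10,000)
simulated from the fitted null, using the asymptotic p-value. This is
a *gate*: mixture components are only promoted to WGD candidates when
the K-S test rejects, so mixture overfitting cannot by itself create a
candidate.

A calibration subtlety: when the null is refitted on the same sample
being tested (the common workflow), the test inherits
Lilliefors-type conservatism — the fitted null chases the data, the
statistic shrinks, and the realised type-I rate falls essentially to
zero. This is safe (never anticonservative) but means the nominal α is
an upper bound in the refitted workflow. The package's type-I
calibration is therefore measured against a *known* null model
(`ksNullModel()`), where the realised rejection rate at α = 0.05 sits
near nominal (≈ 0.04 over 200 replicates in the acceptance battery).

## Mixture models and peak calling

`fitKsMixture()` fits Gaussian mixtures to the in-window ages by EM
for K = 1…4 components, with 10 restarts per K from k-means++-style
initial means, selecting K by BIC. The EM stops on a relative
log-likelihood change below 1e-6 or after 250 iterations; restarts
still crawling at the cap are invariably overfitted K values that lose
the BIC comparison, so the cap only bounds runtime. `callPeaks()`
reports a component as a peak when its weight is ≥ 0.05 and the fitted
total density has a local maximum within one component-sd of the
component mean; each peak's location is the median of the observations
assigned to it by maximum posterior responsibility, with a 95%
nonparametric bootstrap CI (200 resamples). Statuses are
`WGD-candidate` (peak, K-S gate rejected, median ≤ 2),
`needs-corroboration` (median > 2), or `background`.

# Ortholog divergence and placement

`reciprocalBestHits()` computes RBH orthologs between two species
(best hit by bitscore, ties broken by identity and then lexicographic
subject id, reciprocality required), and `orthologDivergence()`
summarises their Ks distribution; its median dates the species
divergence on the same Ks scale as the paralog peaks. `placeWgd()`
compares a peak median with the ortholog median: older ⇒ `shared` WGD,
younger ⇒ `after-divergence`, within the `margin` (or with overlapping
CIs) ⇒ `unresolved`. The margin and CI arguments exist because both
quantities are estimates; the defaults (margin 0, no CI) reproduce the
plain rule.

# Gene-tree sorting (MAPS)

## Subtree collection and the occupancy rule

The species tree must be a ladder (pectinate); `speciesIndex()` labels
its internal nodes N1 (shallowest) … N(k) (root). For each gene tree,
`collectSubtrees()` walks from each species node's clade: a *subtree*
is a maximal gene-tree clade whose taxa lie within the species clade
and cover at least `ceiling(occupancy × clade size)` of its taxa
(default occupancy 45%); the ceiling means e.g. a 3-taxon clade needs
2 observed taxa. A subtree counts as a *duplication* at that node when
both children of its root meet the occupancy requirement and their
taxon sets overlap (the species-overlap criterion). `mapsProfile()`
aggregates counts over thousands of trees into per-node duplication
percentages.

## Null and positive simulations

Observed duplication fractions mean little without a reference:
topological noise and birth–death gene turnover create apparent
duplications at every node. `buildNullSet()` simulates gene families
along the species tree under a linear birth–death process at rates
estimated from the observed gene counts (`estimateRates()`), and
`buildPositiveSet()` adds a WGD at the tested node with retention
probability `r` (default 0.2, a typical paleopolyploid retention
level). Default set sizes are 3,000 simulated trees, subsampled to
1,000, with 100 resamples; the acceptance battery scales these to
600/200/20 to keep runtimes at desk scale — the statistical logic is
size-independent.

## Episode classification

For each node, `fisherVsNull()` runs a one-sided Fisher exact test
(observed vs each null resample, alternative "greater", α = 0.01); the
node shows a *burst* when ≥ 95% of resamples reject. Aggregating
per-resample tests (rather than pooling resamples) keeps the null's
sampling variability in the reference distribution. A burst is
*WGD-consistent* when, additionally, ≥ 50% of positive-set resamples
fail to reject in the other direction (`fisherVsPositive()`), i.e. the
observed excess is statistically consistent with a retained WGD of the
assumed size. Tests at the shallowest and root nodes are reported with
a `lowConfidence` flag — few possible subtree configurations exist
there, so both false positives and false negatives are more likely. No
multiple-testing correction is applied across nodes; the
positive-consistency requirement and the resample-fraction rule are
the operative error controls.

# Birth–death simulator and rate estimation

`simulateGuestTree()` grows a gene family along the species tree under
a linear birth–death process (rates per gene per unit branch length),
with optional WGD events (node, position on the stem branch, retention
probability). With `requireAllTaxa = FALSE` draws are unconditioned
and extinct families return `NULL` — this matters for calibration,
because conditioning on survival inflates mean copy number above the
theoretical E[copies] = 1 at λ = μ. `estimateRates()` recovers λ and μ
from per-taxon gene counts by maximum likelihood on the linear
birth–death transition probabilities. Rate identifiability improves
with tree depth: on short branches almost no events occur and λ, μ are
confounded; the acceptance battery therefore uses a 6-taxon ladder
with tip depths 50–250 time units at λ = μ = 0.002, where both rates
are individually recoverable.

# Total evidence

`totalEvidence()` applies explicit rules per candidate placement:
conflicting placements ⇒ `none` (with a conflict flag); Ks peak +
ortholog support + MAPS support ⇒ `WGD`; Ks + ortholog support with
MAPS explicitly negative ⇒ `significant-burst`; any two supporting
lines ⇒ `WGD`; fewer ⇒ `none`. The distinction between "MAPS not
available" (`NA`) and "MAPS negative" (`FALSE`) is intentional:
absence of gene-tree corroboration downgrades nothing, but an
affirmative background classification does.

# Determinism

All stochastic steps (simulations, EM restarts, bootstraps, K-S null
samples) draw from seeds supplied explicitly; `deriveSeeds()` expands
one master seed into independent stream seeds (all below 2^31), and
every public function restores the caller's RNG state. Two runs of
`runSyntheticPipeline()` with the same seed produce byte-identical
output files.
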