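---
title: "Methods: SSR diversity, structure and core collections with ssrcore"
author: "ssrcore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR diversity, structure and core collections with ssrcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ssrcore re-implements, as one tested toolkit, the analysis chain of a
microsatellite (SSR) characterization of a field-genebank germplasm: the kind
of study in which a few hundred conserved individuals from a handful of
controlled crosses are genotyped at ~100 codominant SSR loci, their diversity
and population structure described, and a core collection extracted for
cheaper conservation. The concrete system the defaults emulate is a
186-palm oil-palm (*Elaeis guineensis*) collection of 12 full-sib families
(selfings, sib-matings and outcrosses) genotyped at 107 SSRs. This vignette
explains the models and estimators, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where the field admits more than one.

## Data model

A `genotype_dataset` is an individuals x loci table of unordered diploid
allele pairs. Allele labels are opaque positive integers (fragment sizes);
pairs are stored in ascending canonical order so datasets compare by
equality, and `0` is reserved as the file-level missing code (stored
internally as `NA` in both allele matrices). Missing data are always handled
by locus-wise complete cases — each statistic's denominator counts only the
typed genotypes of the relevant group — never by imputation. I/O covers the
GenAlEx codominant CSV dialect (three header rows, two allele columns per
locus) and the STRUCTURE two-rows-per-individual text format (`-9` missing).

## Diversity statistics

For an allele-frequency vector $p$ at one locus:

* $A$ = number of observed alleles; $A_e = 1/\sum p_i^2$ (effective alleles);
* $I = -\sum p_i \ln p_i$ (Shannon information, natural log);
* $H_e = 1 - \sum p_i^2$ (expected heterozygosity / gene diversity);
* $PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (Botstein form, always
  $\le H_e$);
* $H_o$ = fraction of typed individuals that are heterozygous;
* $F = (H_e - H_o)/H_e$, defined 0 at monomorphic loci.

$H_e$ is the *plain* gene diversity, matching the convention of the standard
population-genetics spreadsheet tools for codominant data; the unbiased
$2n/(2n-1)$ variant is available via `unbiased = TRUE` but off by default.
Per-population tables average each index over loci (unweighted), sum private
alleles (PA: alleles seen in exactly one population), and append a Mean/Total
row. If every locus of a population is monomorphic its mean $F$ is reported
as `NA` rather than 0.

## Differentiation

`nei_distance()` is Nei's (1972) standard distance
$D = -\ln\left(J_{xy}/\sqrt{J_x J_y}\right)$ with the gene identities averaged
across loci before the ratio. `pairwise_fst()` is the gene-diversity (GST
style) form: per locus $H_T$ from the unweighted mean of the two frequency
vectors and $H_S$ the mean of the two gene diversities, combined as
$(\sum H_T - \sum H_S)/\sum H_T$; Weir–Cockerham $\theta$ is deliberately out
of scope. `gene_flow()` is the island-model estimate $N_m = 0.25(1-F_{ST})/F_{ST}$.
On that point the published characterization of this germplasm is internally
inconsistent: it reports an overall $N_m$ of 1.117 alongside a mean pairwise
$F_{ST}$ of 0.120, yet the island-model formula gives 1.833 at 0.120 (1.117
corresponds to $F_{ST} \approx 0.183$). ssrcore simply computes the formula
from whatever differentiation statistic it is given.

AMOVA decomposes the matrix of pairwise squared genetic distances: the
codominant metric is half the squared Euclidean distance between allele-count
vectors (so identical genotypes score 0, `ii` vs `jj` scores 4, etc.),
summed over pairwise-complete loci; a binary band-presence substrate is
available for dominant-style data. Sums of squares follow the classic
distance form ($SS_{total} = \sum_{i<j} d^2/N$, within-population terms
likewise per group), variance components use the unequal-size coefficient
$n_0 = (N - \sum n_k^2/N)/(k-1)$, a negative among-population component is
truncated to zero, and $\Phi_{PT} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$.
Significance is tested by permuting individuals among populations with sizes
fixed, with `>=` comparison and +1 smoothing, so the smallest attainable
p-value is $1/(n_{perm}+1)$. The permutation stream is seeded, making
p-values reproducible.

## Clustering and ordination

Individual-level distances are computed on the band expansion of the
genotypes: Dice / Nei & Li dissimilarity $1 - 2a/(2a+b+c)$ on band presence,
or Bray–Curtis $1 - 2\sum\min(x,y)/\sum(x+y)$ on 0/1/2 allele copy counts;
loci missing in either member of a pair are excluded for that pair. UPGMA is
implemented directly (average linkage with size-weighted updates, node
height = merge distance / 2) because reproducible dendrograms need an
explicit tie-break: among equally close pairs the one whose label-sorted
cluster representatives are lexicographically smallest merges first. Trees
serialize to Newick with 6-decimal branch lengths; tests cross-check the
cophenetic matrix against `hclust(..., method = "average")` and a naive
$O(n^3)$ re-implementation. PCoA is the Gower double-centring
$B = J(-\tfrac12 d^2)J$ followed by `eigen()`; coordinates are returned for
positive eigenvalues only, negative eigenvalues are reported unchanged, and
percent variance uses the positive-eigenvalue sum as denominator
(cross-checked against `cmdscale`).

## Bayesian admixture and model choice

`gibbs_structure()` is an admixture-model Gibbs sampler with *independent*
cluster allele frequencies: each allele copy carries a latent cluster
assignment $z$; $P_{k\ell}\sim\mathrm{Dirichlet}(\lambda=1)$,
$Q_i\sim\mathrm{Dirichlet}(\alpha)$, and $\alpha$ takes a reflected-normal
Metropolis step (step 0.05, start 1) under a uniform $(0,10)$ prior. The
correlated-frequencies F-model is intentionally omitted: for strongly
diverged SSR clusters the independent model separates groups reliably and is
much simpler to audit. The per-sweep data log-likelihood given the current
assignments is recorded after burn-in, and
`lnpd_estimate()` summarizes a run as $\overline{\ell} - \mathrm{Var}(\ell)/2$
with the population (1/n) variance. Runs use R's RNG, so a seed fixes the
whole trajectory. Label switching is handled by comparing runs only through
label-invariant quantities (lnPD, maximum membership); per-run Q matrices are
reported as-is.

`evanno_delta_k()` computes $\Delta K = |L''(K)| / \mathrm{sd}(L(K))$ over
replicate runs and selects the interior maximum. Defaults are desk-scale —
burn-in 500, 1500 retained sweeps, 3 replicates per K — roughly thirty times
shorter than the 10,000/50,000 settings typical of publication runs; the
longer settings are plain arguments. On synthetic data with three
well-separated founder groups, the desk-scale scan recovers the planted K in
at least 8 of 10 seeded repetitions (this is a tested property); on the
default 12-family collection, whose eight founder groups are hierarchically
related through shared families, a short scan may instead flag a coarser
level first — the K=1..12 scan in `analysis/05_structure.R` recovers K = 8.

## Core collections

Allelic coverage CV is the fraction of the collection's distinct
(locus, allele) classes carried by a subset. Two optimizers are provided:

* `mstrategy_core()` — greedy maximization: repeatedly add the accession
  covering the most uncovered alleles (ties: higher band richness, then label
  order), then remove redundant entries in reverse insertion order. It always
  terminates at CV = 1 and, on small fixtures, matches the exhaustive minimum
  cover; it makes no attempt to stay at a given sampling intensity.
* `localsearch_core()` — fixed-size random-descent: single entry/non-entry
  swaps, accepted iff CV strictly increases, coverage ties broken toward a
  higher mean entry-to-entry distance, stopping after `max_stall` (default
  2000) consecutive rejections. `core_intensity_scan()` sweeps intensities
  (default 20–35% in 1% steps) and reports the smallest reaching CV = 1.

Cores are evaluated by the standard distance criteria (A-NE, E-E, minimum
and mean E-NE; Bray–Curtis by default) and validated against the whole
collection by Welch t-tests on per-locus index values (A, Ae, I, Ho, He, F;
a paired variant is available), per-locus chi-square tests of core allele
counts against expectations scaled from whole-collection frequencies
(expected categories below 1 pooled), the $R^2$ of core vs whole allele
frequencies over all allele classes, and a UPGMA tree of the entries.

One behavioural finding worth knowing: on the synthetic germplasm the
local-search core at ~31% intensity preserves all six diversity indices
(no significant t-test differences), while the greedy minimal core — only
~14% of the collection under the default conditions — significantly raises
$H_o$ and drives $F$ further negative, because covering every allele with as
few palms as possible systematically picks heterozygous, allele-rich
individuals. The frequency-spectrum indices (A, Ae, I, He) remain preserved.
This is a property of minimal covers, not a defect of the search.

## The synthetic germplasm generator

Because the original genotypes are not public, `simulate_germplasm()` is a
first-class module: it draws per-locus allele sets of 3–16 alleles, gives
each of 8 founder groups an independent symmetric-Dirichlet frequency
profile (concentration = `founder_divergence`), and builds 12 families of
sizes 20, 8, 19, 12, 20, 8, 13, 18, 5, 12, 31, 20 (186 palms) by the three
mating designs: selfing (one founder crossed with itself), cross-mating (two
founders), and sib-mating, where the supplied pair acts as grandparents whose
two full-sib offspring are crossed — so inbreeding arises mechanistically,
not by formula. Several families share a founder group (the default map is
596 | 597 | {598, 601, 603} | {599, 602} | 600 | {604, 605} | 606 | 607),
mirroring the eight genetic clusters reported among the twelve crosses.
All offspring alleles derive from founder alleles (no mutation — one
generation makes it negligible and keeps allele sets closed for coverage
tests), loci are unlinked, and missing calls are injected i.i.d.
(default rate 0.01).

`founder_divergence = 1` was fixed once, on realism grounds: it yields a
whole-collection allele count (~8.6 per locus, ~926 classes) matching the
magnitude reported for the real germplasm (8.67, 928). Two realities of the
strict two-founder pedigree should temper extrapolation from passing tests to
real data. First, a family can carry at most 4 alleles per locus, so
per-population allele counts stay near 2, below the published per-population
means (up to 6.4) — real crosses evidently carry more effective founder
lineages or scoring-induced allele inflation. Second, founder-sampling drift
alone puts between-family $F_{ST}$ near 0.3 regardless of group divergence,
above the published mean pairwise 0.120. Statistics that depend on those
magnitudes (pairwise FST levels, AMOVA percentages) are therefore checked
against internal oracles and monotonicity properties, not against the
published values; the published-value checks use the printed tables
themselves as input.

## Problem sizes and determinism

The test suite runs everything at desk scale by choice: the default
186 x 107 collection for end-to-end runs, 10-seed repetitions for
stochastic properties, 200 small datasets for permutation calibration
(99 permutations each), 25-leaf matrices for the UPGMA oracle, and the
desk-scale MCMC settings above. `run_pipeline()` derives one seed per stage
from the global seed (`seed + 100 * stage_index`), writes every table with
fixed formatting (3 decimals for indices, 1 for percentages, 6 for
coordinates and branch lengths), and is byte-identical across repeated runs
with the same config — which the acceptance suite asserts file by file.

## Known limitations

* Two-level AMOVA only (no regional nesting); no bootstrap CIs on FST or He;
  no rarefaction-corrected allelic richness.
* The admixture sampler has no LOCPRIOR/popinfo variants and no CLUMPP-style
  label alignment across runs.
* The generator is single-generation, unlinked and mutation-free; it cannot
  reproduce per-family allele counts above 4 or the low between-family FST
  of the real collection (see above).
* Dendrograms and ordinations are exported as data (Newick, CSV); no
  graphics are produced.
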