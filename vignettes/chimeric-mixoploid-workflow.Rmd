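---
title: "Analysing chimeric, mixoploid blade genotypes: models, choices and limits"
author: "ChimeraPopGen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing chimeric, mixoploid blade genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChimeraPopGen)
```

## 1. The data-generating biology and what it does to genotypes

In the Bangiaceae life cycle a microscopic sporophyte (the conchocelis
phase) releases conchospores; meiosis of one conchospore yields a tetrad
whose four products divide mitotically into a *single* leafy blade. A
blade is therefore a chimera of up to four meiotic genotypes, and blades
can in addition contain more than one ploidy level (mixoploidy). DNA
extracted from a blade slice amplifies the union of the alleles present in
the sampled cells. Two consequences drive everything in this package:

* Per microsatellite locus, an individual is a **set of distinct allele
  sizes** (here capped at 8), not a genotype with known dosage. Because the
  four tetrad products jointly carry every allele copy of the parental
  sporophyte, the blade's observable set equals the sporophyte's
  distinct-allele set: a diploid sporophyte can show up to 2 alleles, a
  tetraploid up to 4, an octoploid up to 8.
* The true ploidy of the genotyped tissue is unknowable (the slice is
  destroyed by extraction), so any dosage model is an *assumption* to be
  stress-tested, not estimated.

The analysis strategy is to run everything under assumed ploidies 2x, 4x
and 8x and ask how much the scientific conclusions move. Statistics that
barely move are robust to the unknown ploidy; this is the package's
central workflow (`runPipeline()` assembles the cross-ploidy comparison).

## 2. Assumed-ploidy recoding

`recodeDataset(ds, m, seed)` retains each observed allele set unchanged
when it fits within `m` distinct alleles, and otherwise draws a uniform
random `m`-subset. Two details matter:

* **Order independence.** The subset index is drawn from a stream keyed by
  a 32-bit FNV-1a hash of `(seed, individual_id, locus)`, so the retained
  subset for a given cell is identical whatever else is in the dataset and
  in whatever order cells are processed. Candidate subsets are enumerated
  in lexicographic allele order. Uniformity of the draw across seeds is
  property-tested (a 3-allele set at m = 2 yields each of the 3 pairs with
  frequency 1/3).
* **Subsampling replicates.** Whether to subsample once or average over
  draws is genuinely open; the AMOVA takes a `replicates` argument
  (default 10) and reports means and SDs over dosage/subsample
  resolutions, so the reader sees the Monte-Carlo spread rather than one
  arbitrary draw.

Cells are flagged `ambiguous` when the retained set does not pin down the
dosage under ploidy `m` (any multi-allele set at m > 2, or a set strictly
between 1 and m alleles). The flag is conservative metadata: a set of
exactly m alleles at m > 2 has a single compatible dosage (one copy each)
and downstream code works from the compatible-multiset enumeration, not
from the flag.

## 3. The EM dosage correction

For one population and locus, `emAlleleFrequencies()` maximises the
likelihood of the observed allele sets ("phenotypes") under a genotype
prior that is the multinomial random union of `m` gametes at the current
frequencies — the Hardy–Weinberg analogue for ploidy m. The E-step puts
posterior weights on the dosage multisets compatible with each phenotype
(every observed allele at least once, nothing unobserved —
`enumerateCompatibleGenotypes()`); the M-step re-estimates frequencies
from expected allele counts.

Numerical choices: initialisation is uniform over the observed alleles;
iteration stops when the largest frequency change falls below `tol = 1e-8`
or at `maxIter = 10000` (non-convergence is flagged on the returned
object, never an error); the log-likelihood trace is returned and is
asserted monotone in the tests. At m = 2 dosage is never ambiguous and the
EM reproduces direct allele counting exactly; at m = 4 it is tested
against a brute-force grid-search MLE whose phenotype likelihood is
computed by inclusion–exclusion, an independent route.

**Selfing is not modelled.** The genotype prior assumes random union of
gametes. Selfing-aware dosage corrections exist (the classical EM for
partially selfing autotetraploid crops estimates a selfing rate jointly),
but the study system's selfing rate is unknown and unidentifiable from
dosage-ambiguous data, so the package takes random mating as the default
and documents the consequence (Section 8).

No inbreeding coefficient is offered at the allele-frequency level for
m > 2: with unknown dosage the observed/expected heterozygote comparison
that defines it has no defensible observed term. (The AMOVA's
*F*~IS~ — a ratio of variance components under the resolved-dosage
expansion — is reported, with its Monte-Carlo spread.)

## 4. Diversity and differentiation

`diversityTable()` reports, per population: mean over loci of
*H*~S~ = 1 − Σp² from the EM frequencies, *EN* = 1/(1 − mean *H*~S~)
(the bijection holds exactly at this averaging level, by construction),
the SD of *H*~S~ over loci, and N. *H*~S~ is deliberately **uncorrected**
for sample size: the usual n/(n−1)-style correction needs a defined number
of allele copies, which dosage ambiguity denies. Comparisons with
small-sample-corrected software outputs are therefore approximate.

`pairwiseDifferentiation()` computes, per population pair and locus,
Hs̄ (mean of the two gene diversities), Ht (gene diversity of the mean
frequency vector), and

* Nei's Gst = (Ht − Hs̄)/Ht, multilocus value the ratio of sums
  Σ(Ht − Hs̄)/ΣHt;
* Jost's D = 2(Ht − Hs̄)/(1 − Hs̄) (pairwise factor k/(k−1) = 2),
  multilocus value the harmonic mean of per-locus D, following Jost's own
  recommendation for combining loci; a non-positive per-locus D makes the
  harmonic mean 0, which we propagate as the limit value. Raw per-locus
  values (including small-sample negatives) are kept in the `perLocus`
  array; nothing is silently clamped.

Both statistics are defined as 0 when Ht = 0 (two populations monomorphic
for the same allele): there is no differentiation to measure.

## 5. The four-level AMOVA

`amova()` expands every individual to `m` allele copies per locus. Cells
whose dosage is ambiguous are resolved by a **uniform draw among the
compatible dosage multisets**, independently per replicate. The
alternative — weighting by the EM posterior — was considered and left out
of the default path: the uniform draw matches the resampling spirit of the
recoding step, keeps the ANOVA machinery standard, and its Monte-Carlo
spread is reported rather than hidden.

Squared distance between allele copies is 0/1 identity-in-state. A
stepwise (repeat-count) metric would be easy to swap in, but nothing in
the workflow's conclusions depends on mutation-model assumptions, and
identity-in-state is the assumption-free choice.

Per locus, sums of squared deviations are computed at the four nesting
levels from allele-count tables (for counts n_a in a cell of n copies,
the within-cell pair sum is C(n,2) − Σ~a~C(n_a,2), divided by n), and the
method-of-moments system is solved with the standard unequal-size
coefficients for a fully nested random model (the Searle-type
cell-size sums). Degrees of freedom and coefficients use each locus's own
non-missing individuals. Multilocus components are the **sums of
per-locus components** — equivalent to pooling sums of squares when the
design is equal across loci, and well-defined under per-locus missingness.
Dispersion is reported two ways (SD over loci of the per-locus F values,
and SD over replicates of the multilocus values) because which of the two
a reader wants depends on whether locus sampling or dosage resolution is
the uncertainty of interest.

Conventions at the edges, chosen once and tested:

* components may be negative (method of moments) and are propagated;
* percent variance always sums to 100;
* if the total variance is 0 (all copies identical) every F is NaN with a
  warning;
* a 0/0 F-ratio with positive total variance is reported as 0 (e.g.
  F~SC~ when all variance is among groups);
* a group containing a single population is an error with instructions to
  merge or drop — its among-populations component is undefined;
* **no permutation p-values**: when the grouping being tested was itself
  derived from a clustering of the same genotypes, a permutation test of
  that grouping is circular. The package refuses to offer one.

The F-statistics are F~CT~ = σ²~a~/σ²~tot~, F~SC~ = σ²~b~/(σ²~b~+σ²~c~+σ²~d~),
F~IS~ = σ²~c~/(σ²~c~+σ²~d~), F~IT~ = (σ²~a~+σ²~b~+σ²~c~)/σ²~tot~, with
a = among groups, b = among populations in groups, c = among individuals
in populations, d = within individuals.

## 6. PCA, cluster-number selection, hierarchies

`pcaGenotypes()` builds an individuals × (locus, allele) matrix in which
each allele retained at a locus carries weight 1/|retained set|, so every
scored locus contributes total weight 1 regardless of how many alleles a
chimeric blade shows. Missing loci are imputed with the **population**
column mean (global mean by flag): population-mean imputation prevents
missingness patterns from masquerading as structure on the leading axes.
Columns are centred, and the covariance eigendecomposition is delegated to
`prcomp`.

`evannoDeltaK()` computes, for interior K, the mean over replicates of
|L(K+1) − 2L(K) + L(K−1)| divided by the SD of L(K) over replicates. It is
translation-invariant in L, undefined at the boundary K, and errors
loudly when the replicate SD is zero rather than dividing by it.
Replicates are paired by input order within K; the selected K (argmax) is
invariant to run order, which is the property tests assert.
`ancestryByPopulation()` aligns cluster labels across replicates by greedy
correlation matching to the first replicate — adequate at the K values
used here; a full label-switching solver is out of scope and a weak
alignment (correlation < 0.5) warns.

Hierarchies for the AMOVA are **declared, not inferred**. The helper
`maxAncestryHierarchy()` converts a chosen-K ancestry matrix into a
population → group map by modal assignment and flags, for exclusion,
individuals confidently assigned (max ancestry ≥ 0.5) to a cluster other
than their population's modal one — the generic form of removing stray
other-species genotypes before within-species analyses.

## 7. cpDNA haplotypes and the network

`collapseHaplotypes()` merges identical aligned sequences; under the
default policy IUPAC ambiguity codes act as wildcards and a record joins
the first haplotype it is compatible with (the representative kept is the
member with fewest ambiguities). Gaps are treated as a fifth state —
the coding-region alignments this targets are gap-free, and a flagged
site-exclusion alternative would silently shrink the compared length.
`pairwiseSteps()` is the Hamming distance over mutually determined sites.

`minimumSpanningNetwork()` grows the network Kruskal-style over distance
classes in increasing order, adding **every** edge that joins two
components distinct at the start of the class — so equally short
alternative connections are retained (a network, not a tree). The
`maxSteps` cap excludes longer edges and can leave divergent haplotypes
isolated. This is a deliberate, documented approximation to a statistical
parsimony connection limit: the probability recursion behind the
classical 95% limit is not re-implemented, because a divergent haplotype's
isolation is reproducible with the cap alone and a re-derivation risks
silent disagreement with the established tools readers will compare
against.

## 8. The simulator: what it emulates and what it does not

`simulateDataset()` is a forward generator with known truth, built so
every downstream stage has a parameter-recovery test:

* **Frequencies.** Per locus, a root frequency vector over the allele grid
  (offset + k·repeat unit) is drawn symmetric-Dirichlet(1); species pools
  are Balding–Nichols children of the root with parameter
  `speciesDivergence`; clusters of species with `fctSim`; populations of
  clusters with `fscSim`. A zero parameter copies the parent exactly, so
  each parameter is the Wright-style F its AMOVA layer should recover
  (tested: fct 0.25 recovered within ±0.05, fsc 0.10 within ±0.03).
* **Blades.** Sporophyte ploidy ~ `ploidyWeights` over {2, 4, 8}; each
  locus gets ploidy/2 maternal + ploidy/2 paternal gamete draws; the blade
  observes the distinct-allele union, each allele dropped with
  `dropoutProb`. Dropout deliberately subsumes both PCR dropout and
  unsampled chimera sectors — one parameter, one testable rule. Mixed
  ploidy *within* one blade is not separately modelled: the observable
  union of, say, a 2x+4x mosaic is indistinguishable from a single
  suitable sporophyte, so the extra mechanism would add parameters without
  adding observable structure.
* **Hybrids and cpDNA.** With probability `hybridFraction` the paternal
  gamete pool is the other species; cpDNA is maternal, drawn from a
  population pool of `cpHapsPerPool` sequences one substitution step from
  a species root (star-like, matching shallow empirical networks), and
  hybrid-lineage blades carry the other species' haplotype with
  probability `introgressionProb`.
* **Defaults** describe the emulated study system: 2 species × 2 regional
  clusters × 3 populations × 18 blades, 10 trinucleotide loci with up to 8
  alleles, divergence 0.25/0.20/0.08 (species/cluster/population), ploidy
  weights (0.5, 0.35, 0.15), 2% hybrids, 50% introgression along hybrid
  lineages, 5% dropout, 1141 bp cpDNA. Selfing (default 0.1) is accepted
  for interface completeness but under within-population panmixia it does
  not change the allele-copy distribution.

Not emulated: coalescent ancestry, linkage, microsatellite mutation during
the simulation, selection, spatial geography/isolation-by-distance, and
within-blade ploidy mosaics beyond the union rule. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model — not robustness to, e.g., null alleles or scoring error in real
chromatograms.

**Known limitation: Hs under a misspecified assumed ploidy.** When the
assumed ploidy exceeds the truth, the random-mating dosage EM sees far
more single-allele phenotypes than an m-ploid Hardy–Weinberg population
would produce and reconciles this by skewing the frequency estimates, so
plug-in *H*~S~ shrinks systematically as the assumed ploidy grows (on a
two-allele diploid-truth locus with p = 0.8, the asymptotic plug-in
*H*~S~ is 0.32 at 2x but 0.17 at 8x; simulated datasets at realistic
diversity show mean drifts of several hundredths to ~0.1 between the 2x
and 8x codings). Two things survive this bias, and they are what the
workflow relies on: the *ranking* of populations by diversity (tested),
and the differentiation statistics, whose numerator and denominator are
distorted together (the cross-ploidy F~CT~ spread on study-scale
simulations is below 0.01). A selfing-aware prior would absorb part of
the homozygote excess and soften the drift; it is deliberately out of
scope (Section 3).

## 9. Problem sizes used in the test-suite

The shipped tests run the full battery at sizes chosen to make sampling
noise small relative to the asserted tolerances while staying desk-scale:
the ploidy-robustness replay uses 440 blades × 10 loci under all three
codings; parameter recovery uses 8 populations × 20 blades × 10 loci;
EM recovery uses 500 autotetraploids; the subsampling-uniformity property
uses 6000 seeds; everything else is toy-sized with exact expectations.
`scripts/acceptance.R` re-runs the same battery end-to-end from a single
command-line seed.
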