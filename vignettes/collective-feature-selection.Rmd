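---
title: "Collective feature selection for epistatic variants: models and methods"
author: "epiCollect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective feature selection for epistatic variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiCollect)
```

## The problem

Epistatic (non-additive, multi-locus) effects on case/control traits are
notoriously hard to screen for: the pair search space is quadratic in the
number of SNPs, and no single feature-selection algorithm is sensitive to
every genetic architecture. A parametric penalized regression sees what its
design matrix encodes; a Relief-family scorer sees local neighbourhood
structure; an exhaustive MDR scan sees cell-level case/control imbalance;
tree ensembles see hierarchical splits. Their top-ranked variants overlap
surprisingly little.

`epiCollect` implements the *collective* strategy: run several
heterogeneous rankers, take the top *k*% of variants from each, and carry
the **union** forward to downstream modelling. Because the union contains
every per-method selection, its sensitivity (fraction of truly causal
variants captured) is bounded below by the best single method — a
set-inclusion fact the test suite asserts on every benchmark row rather
than estimates.

The package also contains everything needed to benchmark the strategy
without external data: two genotype simulators, truth manifests, and a
sensitivity-based evaluation harness.

## Rankers

All selectors implement one contract: `rankFeatures(dataset, method,
config)` returns a `FeatureRanking` with one finite score per SNP and a
total order (ties broken by ascending column index everywhere in the
package — deterministic and seed-independent).

**MDR (`mdr`).** Every one-locus and two-locus model is scored by
*training* balanced accuracy, without cross-validation: a genotype cell is
labelled high-risk iff its case:control ratio strictly exceeds the
dataset-wide ratio (implemented integer-exactly as
`cases(cell) * nControls > controls(cell) * nCases`), and
BA = (TPR + TNR)/2 with high cells predicting case. Empty cells and exact
ties are low-risk — a conservative, deterministic convention. A feature's
score is the best BA over all models containing it (the simplest monotone
way to turn model ranks into feature ranks; `mdrRank()` also returns the
full model table so other extraction rules can be compared, and
`mdrModel()` materialises any single model with its cell labels). The
two-way scan is computed with 18 indicator cross-products, so the
quadratic model space costs three dense matrix multiplications per
genotype pair rather than an explicit loop.

**MultiSURF\* (`multisurf_star`).** A Relief-family scorer with
per-instance distance thresholds. Attribute difference is range-normalised
(|a−b|/2 for 0/1/2 genotypes); instance distance is the mean attribute
difference. For target *i*, the threshold is the mean distance to all
other instances, with a dead band of half the standard deviation of those
distances on each side: nearer neighbours are *near*, farther ones *far*,
the band is ignored. Near pairs score conventionally (miss +diff, hit
−diff), far pairs invert the update (miss −diff, hit +diff), and scores
are divided by the sample count. If the distance distribution around an
instance is degenerate, all its neighbours fall in the band and it
contributes nothing (not an error). The O(n²p) double loop is compiled
(Rcpp); the test suite checks it to 1e-12 against a literal, loop-based R
transcription on over a hundred random datasets.

**TuRF wrapper (`turf`).** Recursive elimination around any base ranker
(MultiSURF\* by default): re-rank the survivors, drop the lowest-scoring
`floor(dropFraction * current)` features (at least one) per iteration,
stop at `minFeatures`. The final order lists survivors by their
last-iteration scores, then removed features in reverse removal order
(later-removed ranks higher); removed features carry synthetic
strictly-decreasing scores so the order/score consistency invariant holds.
Drop fractions of 1%, 5% and 10% are the grid of interest; 10% is the
default, and `minFeatures` defaults to a tenth of the features so a
top-10% selection always comes from genuinely surviving features.

**Random forest (`rf`) and gradient boosting (`gbm`).** Delegated to
`ranger` and `xgboost` behind the same contract. The `"main"` preset uses
1000 trees with 35 variables per split and 800 boosting trees; the
`"interaction"` preset uses 4500 trees with 70 variables per split (200
beyond 100 SNPs) and 15000 boosting trees; boosting always uses shrinkage
0.01 and bag fraction 0.5. Forest importance is permutation-based by
default (configurable to impurity); boosting importance is total
loss-reduction (gain), with never-used features scored 0. Boosting depth
is 2 by default — stumps cannot represent a pure interaction, and depth-2
trees admit one genotype–genotype split nesting. Both learners are
seeded per call and reproducible; unlike MDR and MultiSURF\* they are
*not* invariant to reordering samples (the bootstrap draws change), which
the test suite reflects by asserting order-invariance only for the
deterministic scorers.

**Penalized regression (`lasso`, `lasso_int`, `enet`).** `glmnet` paths
with the penalty weight chosen by 5-fold *stratified*, seeded
cross-validation at the loss minimum (not the 1-SE rule). The default loss
is logistic deviance — the binary-appropriate choice — with
`family = "gaussian"` available for a squared-error objective.
`lasso_int` expands the design to all p + p(p−1)/2 main and pairwise
product columns (`buildInteractionDesign()`), standardises every column,
drops and records constants, and attributes each interaction coefficient
back to both member SNPs: a feature's score is the largest absolute
coefficient among its main term and all products containing it, so either
member of a selected interaction is promoted. `enet` uses mixing
α = 0.5 on the main-effects design (an `interactions` flag expands it).

## The collective step

`topFraction()` takes k = max(1, round-half-up(p/100 · n)) features from
the head of a ranking. On the study grid (2/3/5/10% of 100 or 500 SNPs)
k is integral; the rounding convention only matters off-grid.
`collectiveUnion()` applies the percentage *per method*, forms the union
and (for comparison) the intersection, and records which methods selected
each feature. Nothing is weighted or fused — the method is a plain union,
and the package deliberately offers no rank-aggregation alternative.

## Simulator 1: frequency-shift case/control data

`simulateFreqData()` builds balanced datasets in which causal SNPs have
different (joint) genotype frequencies in cases versus controls, sampled
with replacement. The baseline is Hardy–Weinberg at MAF q (default 0.4);
an enriched main-effect SNP mixes the baseline with a point mass on the
minor homozygote, `(1−s)·HWE + s·1[g=2]`, and an enriched pair mixes the
independent HWE product with a uniform mass on the diagonal cells
{(0,0),(1,1),(2,2)} — the "diagonal" architecture. The mixing weight
s ∈ {0.1, 0.5, 0.9} is the signal-strength grid; s = 0 reduces exactly to
the null, which the calibration tests exploit. The model grid
(`1SNP`–`4SNP`, `case1_control0` … `case2_control2`) fixes causal units at
G1–G4 (case-enriched) and G97–G100 (control-enriched). The source data
this emulates were described only qualitatively (their exact frequency
tables are not public), so the uniform-diagonal mixture is this package's
concrete instantiation: it matches the diagonal naming, is fully
specified, and nulls out at s = 0. Whether the original generator
weighted the diagonal by genotype frequency is unknown; the uniform
choice is a documented convention, not a claim about the original.

## Simulator 2: GAMETES-style pure epistasis

`randomPureEpistasisModel()` draws two-locus penetrance tables f(g1,g2)
that are *pure-strict*: every single-locus marginal penetrance equals the
prevalence K, so no signal is visible marginally. The construction is
exact rather than iterative: with HWE weights w, the six zero-marginal
constraints have rank 5, leaving a 4-dimensional deviation space whose
orthonormal basis is computed once by eigendecomposition; a random
Gaussian direction in that space is scaled so the penetrance-based
heritability

h² = Σ w(g1)w(g2) (f − K)² / (K(1−K))

hits the target exactly, and the draw is rejected while any penetrance
leaves [0, 1]. Marginals are flat to 1e-12 and h² exact to 1e-9 by
construction, which the acceptance tests assert.

**Ease of detection.** Equal-h² models differ enormously in how easy they
are to find. The package stratifies model populations by the analytic
Bayes-optimal two-locus balanced accuracy

BA\* = 0.5 + 0.25 · Σ_cells |P(cell|case) − P(cell|control)|,

a closed-form, monotone-in-detectability score with clean bounds (0.5 for
a constant table, 1 for the fully-penetrant XOR model at MAF 0.5 — both
frozen as tests). `selectEdmExtremes()` scans a candidate population
(10,000 models by default) and returns the minimum (*hard*, EDM-1-like)
and maximum (*easy*, EDM-2-like) scoring models.

**Adding the main effect.** The third predictive locus carries an
additive penetrance, f(g) = K + c·(g − 2q), scaled to a target h².
Combining it with the pair follows the GAMETES convention of *additive
model combination*: the 27-cell table is the weighted average
(1−w)·f_epi(g1,g2) + w·f_main(g3) (weight 1/3 by default — one of three
predictive loci), which stays in [0, 1] by convexity and whose
heritability is computed exactly from the variance sum of the two
independent-locus deviation components. The heritability grid
{0.1, 0.2, 0.4} names the *component models'* h², as in GAMETES model
files; the realised heritability of the combined table (reported by
`heritability()`) is smaller. The alternative reading — rescaling both
components so the combined table's total h² equals the grid value — is
provably empty at h² = 0.4 and MAF 0.2: a 400,000-draw scan over
prevalences 0.2–0.7, main-effect shares up to 1/3 and both signs of the
additive direction found no 27-cell table inside [0, 1], because the
additive deviation at the rare minor homozygote is 2.83 standard units.
That analysis fixed this design.

**Prevalence.** GAMETES leaves K model-dependent, and feasibility demands
it here too: achievable pure-strict h² at MAF 0.2 tops out near 0.33 at
K = 0.25 but near 0.45 at K = 0.4, while an additive single-locus effect
caps at h² = (1−K)/(8K). The defaults therefore adapt — pair
K = 0.25 + 0.5·(h²−0.1) clamped to [0.25, 0.45], main
K = min(0.25, 1/(1+8.8 h²)) — and both are explicit arguments.

**Sampling datasets.** All 100 SNPs (97 noise + 3 predictive) are drawn
i.i.d. from HWE at MAF 0.2 — noise at the same MAF as signal, so nothing
distinguishes them marginally. Disease status is assigned by the 27-cell
penetrance and individuals are accepted into whichever class quota
(1000/1000) is open; because candidates are i.i.d., the accepted cases
are an i.i.d. sample from P(cell|case) regardless of when the quotas
fill, which a 100,000-sample Monte-Carlo test verifies against the
analytic class-conditionals. Noise genotypes are drawn after acceptance —
distributionally identical to drawing them per candidate, and cheaper.
Predictive loci sit at columns 1–3 (recorded in the truth manifest); a
`shuffle` flag permutes columns for stress tests.

## Evaluation harness

`selectionSensitivity()` scores a selection as the fraction of the truth
manifest it contains (tp/|causal|), with tp + fp = |selection| by
construction. `runBenchmark()` walks a (model × signal or architecture ×
h²) grid, simulating `replicates` datasets per cell with seeds derived
deterministically from one master seed (so results are independent of
execution order and partial failures are recorded without aborting),
running every selector, and emitting one long-format row per
model × method-or-union × percentage × replicate. For the GAMETES
experiment it also pools, per architecture, the distinct true positives
recovered by the union across the three heritability levels — each
level's three causal loci counted separately, so nine are recoverable per
architecture — and tabulates Venn-region overlaps of the pooled
per-method selections (`overlapCounts()`, 2–4 sets).

Control-enriched pairs in the frequency-shift experiment count as true
positives exactly like case-enriched ones: both are causal by
construction.

## Problem sizes, seeds and numerical conventions

* The benchmark used by the acceptance checks runs the full study
  dimensions per dataset (100 SNPs, MAF 0.2, 1000 cases/1000 controls,
  both architectures, h² ∈ {0.1, 0.2, 0.4}) with 5 replicates per cell
  and 1000-tree forests — the package's desk scale; the study scale
  (50 replicates, 4500 trees) is a configuration change
  (`replicates = 50`, `selector = list(rfTrees = 4500)`).
* Null-calibration tests run 50 replicates of null (s = 0) 4000-sample
  datasets through one ranker per family (MDR, MultiSURF\*, lasso) and
  test every feature's top-10% inclusion count against Binomial(50, 0.1)
  with Holm control at α = 0.01. Inclusion is counted only when the
  selected feature scores above the replicate's no-evidence floor: a
  fully-shrunk lasso (the usual outcome on null data) scores every SNP
  zero, and forcing a top set out of an all-tied ranking exercises the
  deterministic index fallback, not a signal claim. The always-informative
  scorers (MDR, MultiSURF\*) are additionally pinned at exactly 10%
  marginal inclusion.
* All randomness flows through explicit seeds; per-cell seeds are mixed
  from (master, cell, replicate) with 32-bit-safe arithmetic. No global
  RNG state leaks: seeded code paths restore the caller's RNG.
* Tie-breaks everywhere are stable ascending feature index; `topFraction`
  rounds half up with a floor of one; MDR's high-risk rule uses integer
  cross-multiplication, so no floating-point ratio ever decides a label.
* Rejection sampling for pure-strict models caps at `maxRetries` and
  reports infeasibility explicitly rather than degrading the target.

## What the simulations do and do not show

The generators emulate the *statistical* structure of the benchmark:
balanced sampling, HWE genotypes, pure interactions, equal-MAF noise.
They do not emulate linkage disequilibrium, missing genotypes, covariates,
population structure, or quantitative traits — all declared out of scope.
A method ranking that holds on these simulations therefore speaks to
architecture sensitivity, not to robustness against real-data artefacts;
the union's dominance over its members, however, is structural and
carries over to any data.

Known limitations: the frequency-shift tables are a reconstruction of an
informally described generator; the ease-of-detection score is an
operational stand-in for the original measure (monotone in true
detectability but not numerically identical); MDR's feature extraction
from model ranks uses the max rule, one of several defensible choices;
and boosting/forest importances inherit whatever biases their libraries'
estimators carry.
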