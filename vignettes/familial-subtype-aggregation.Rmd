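---
title: "Testing familial aggregation of breast tumor molecular subtypes"
author: "famagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing familial aggregation of breast tumor molecular subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famagg)
```

## Scope and model

`famagg` analyses expression cohorts from breast cancer families that
test negative for *BRCA1*/*BRCA2* germline mutations. Its stages mirror the
standard analysis of such cohorts: tumors are classified into the five
intrinsic molecular subtypes by correlation with subtype centroids; the
family structure is then interrogated for subtype aggregation; basal-like
and luminal-B tumors are screened with linear signature classifiers for a
BRCA1-like or BRCA2-like phenotype; MS-MLPA methylation ratios are
thresholded into promoter methylation calls and related to expression of
the silenced gene; and the cohort's unsupervised structure is summarized by
hierarchical clustering of the most variant genes.

This vignette documents the statistical model behind each stage, the
parameters that matter, the conventions adopted where a choice had to be
made, and what the synthetic-data tests do and do not establish.

## The familial aggregation test

### Statistic

Let families $F_1,\dots,F_m$ contribute $n_1,\dots,n_m$ tumors with
subtype labels. The concordance statistic

$$ S \;=\; \#\{\, i \;:\; F_i \text{ contains at least two tumors of the
same subtype} \,\} $$

counts concordant families. The definition is deliberately coarse: a
three-member family with two luminal-A tumors and one basal-like tumor
contributes exactly as much as one with three luminal-A tumors ("two or
more" is not graded), and singleton families can never contribute.

### Null distribution

Under the null hypothesis that subtypes do not aggregate in families, the
family labels are exchangeable: conditional on the observed multiset of
labels, every assignment of labels to family slots is equally likely. The
null is therefore built by uniformly permuting the pooled labels over the
family slots:

* `permutation_null()` samples this distribution (default 100,000
  replicates, seeded and reproducible);
* `exact_null()` computes it exactly by a memoized recursion over the
  remaining label counts, family by family — each family receives a
  multivariate-hypergeometric composition of the remaining pool. It is
  the brute-force oracle against which the sampler is tested.

The exact routine refuses instances whose multinomial arrangement count
exceeds a configurable budget (default $10^7$); the budget is expressed in
arrangement counts because that is the natural size measure of the
enumeration problem, even though the memoized recursion visits only the
much smaller set of distinct count states. For the eleven-family table
shipped with the package ($\sim 1.5\times 10^{11}$ arrangements) the tests
raise the budget explicitly when they want the exact arbiter.

The empirical p-value is the plain proportion of null mass at or above the
observed statistic, $P(S \ge S_{obs})$. The $(r+1)/(n+1)$ convention is
available behind a flag (`convention = "add_one"`) but is never the
default, so reported values are directly comparable to published
plain-proportion p-values.

### Permutation pool

Which samples enter the pool is a genuine modelling choice.
`pool_policy = "multicase_only"` (the default) pools only the labels of
families with two or more sampled tumors and permutes them over those
families; `"all_samples"` pools every sample over every family. Singleton
families cannot change $S$, but they do dilute the pool and thereby change
the null. The default was chosen because it is the only construction
computable from a table that lists multi-case families alone, and because
on both bundled tables it reproduces the published p-values (about
$1.7\times10^{-3}$ for the eleven-family table and $0.017$ for the
five-family confirmation table, the latter verified against the exact
null). Both policies are implemented and tested.

### Calibration and discreteness

Because $S$ is integer-valued on a short support (0 to the number of
multi-case families), its exact permutation p-value is discrete, and the
test is conservative at conventional levels: with eleven multi-case
families and realistic subtype prevalences, the achievable rejection
probability at a nominal 0.05 is roughly 0.02–0.03 rather than 0.05. This
is a structural property of any exact test on a discrete statistic, not an
implementation artifact; the property tests therefore verify that the
measured type-I error does not *exceed* the nominal level, and that power
is nondecreasing in the within-family concordance of the generator.

## Synthetic cohorts

`generate_cohort()` emulates exactly the structure the analysis assumes:

* **Centroids** — block design: each subtype owns a disjoint set of
  `n_markers_per_subtype` marker genes raised by `delta` over baseline in
  its own centroid column. Default `delta = 2` on the log scale.
* **Families and labels** — each family draws a founder subtype from the
  prevalence vector; each member inherits it with probability `rho` and
  otherwise draws independently. `rho = 0` embeds the exchangeable null
  exactly; `rho = 1` forces perfect aggregation. The founder-mixture form
  was chosen as the simplest mechanism interpolating between those
  extremes; it is a modelling convention, not an empirical claim.
* **Expression** — centroid plus independent Gaussian noise, standard
  deviation `sigma` (default 1), per gene. Independent Gaussian noise on
  the log scale is the standard array assumption; nothing platform-specific
  is modelled.
* **Methylation** — a fraction of samples is marked methylated; their
  promoter-probe ratios are drawn from $U(0.3, 0.8)$ and unmethylated
  ratios from $U(0, 0.1)$, ranges chosen to straddle the conventional 0.2
  positivity threshold unambiguously, and the methylated samples'
  expression of the target gene is decremented by
  `methylation_knockdown`.

Default cohort shape mirrors a familial series of 58 families and 70
tumors (47 singletons, ten families of two, one of three) with prevalence
$(0.13, 0.10, 0.47, 0.26, 0.04)$ over (basal-like, HER2-enriched, lumA,
lumB, normal-like), the distribution seen in such cohorts. The default
`rho = 0` makes the generator a null generator unless aggregation is
requested. Separability defaults (`delta = 2`, `sigma = 1`) are
conventions — no published effect sizes exist for subtype separability on
a given platform — and tests that need near-perfect recovery tighten
`sigma` to 0.5 explicitly.

All draws derive from one master seed through stage-specific streams, so
adding a stage (e.g. methylation) never perturbs earlier draws, and
identical configurations yield byte-identical cohorts.

What the synthetic tests establish: that every stage recovers the
structure it assumes, at the stated effect sizes, and that the aggregation
test is valid and consistent against its enumeration oracle. What they do
not establish: performance on real arrays — real noise is heteroskedastic
and correlated across genes, real subtypes are not equiprevalent blocks,
and real families carry shared environment as well as genotype. The
package deliberately does not simulate probe-level, batch, or copy-number
effects.

## Subtype classification

`classify_cohort()` assigns each sample the subtype whose centroid it
correlates with most strongly. Spearman rank correlation is the default —
the convention of the standard nearest-centroid subtype classifiers —
making calls invariant to any strictly monotone per-sample transform;
Pearson is available by option. Ties are broken toward the first subtype
in the centroid column order, which is therefore part of the centroid file
contract. Zero-variance profiles and constant centroid columns are
rejected with explicit errors rather than producing undefined
correlations.

Published centroid tables (e.g. the 50-gene intrinsic-subtype centroids)
are treated as user-supplied data loaded with `load_centroids()`; the
package bundles none and all tests run on synthetic centroids. Gene
matching (`match_genes()`) aligns matrix and centroids on shared genes and
fails hard below a configurable overlap fraction (default 0.5 of centroid
genes). At load time, duplicate probes for one gene symbol collapse to the
most variant probe — the common convention; the alternative (error) is a
flag. Optional per-gene scaling before correlation exists in some
published implementations; here scaling is not applied by correlation
(rank correlation is scale-free per gene anyway for monotone transforms),
and the standardization utility is separate and explicit.

Percentages in `subtype_distribution()` round half away from zero to
integer percent, matching clinical table style (33/70 prints as 47%).
`subtype_enrichment_test()` is the two-sided Fisher exact test on the
2×2 subtype-by-group table; tests verify it against a fixed-margin
enumeration oracle.

## BRCA-like signature classification

The BRCA1-like (within basal-like) and BRCA2-like (within luminal B)
calls are linear decision rules over a signature gene set:
$\mathrm{score}(x) = w^\top x + b$, positive meaning BRCA-like. Published
signatures with trained weights are loaded as data (`load_signature()`);
`train_signature_model()` fits such a rule from labelled samples with a
soft-margin linear SVM (regularization constant default 1) for synthetic
experiments. Training z-scores each gene with its training statistics and
folds the standardization back into $(w, b)$, so stored models score raw
expression directly and remain a plain linear functional. A score of
exactly zero is assigned the sporadic-like class — the conservative
boundary convention. Predictions are gated: only samples whose assigned
subtype equals the model's `applicable_subtype` are scored; no
probability calibration is attempted (raw margins only).

## Methylation calls

A promoter probe is positive when its MS-MLPA ratio strictly exceeds 0.2;
a ratio of exactly 0.2 is negative. A sample is promoter-positive when
any of its probes is positive — the any-probe rule, chosen because kits
carry several probes per promoter and gene-level positivity must be
summarized somehow; the rule is documented rather than claimed canonical.
`expression_association()` relates methylation status to expression of
the silenced gene with Welch's unequal-variance t-test by default — the
compared groups are typically very unbalanced (a handful methylated
versus hundreds not) — with Student's pooled form behind a flag. At the
6-versus-30 group sizes used in the tests the Welch degrees of freedom are
about 7, which is why the power assertions sit at the 0.01 level.

## Unsupervised structure

The exploratory pipeline runs in the canonical order: select the top $k$
genes by sample variance **on raw values** (standardizing first would
equalize all variances — a forced choice), then standardize each selected
gene to zero mean and unit variance ($n-1$ denominator throughout), then
cluster samples with Euclidean distance and complete linkage. Ties in the
variance ranking break by gene id in C-locale order, making selection
deterministic. $k = 500$ is the customary whole-cohort choice, $k = 200$
for smaller subsets. Trees serialize to Newick text with merge heights so
they diff cleanly in tests; two-dimensional (gene × sample) clustering is
available but off by default, since only the sample tree is required for
group recovery. Heat-map rendering delegates to `pheatmap` when
installed.

## Numerical conventions and problem sizes

* Sample variance uses the $n-1$ denominator everywhere.
* Rounding of display percentages is half-away-from-zero; all stored
  values are full precision.
* Monte-Carlo defaults: 100,000 replicates for reported p-values. The
  property suites use 10,000 generated cohorts for the null-embedding
  goodness-of-fit, 1,000 cohorts per point of the type-I/power grid with
  2,000 null replicates each, and 100,000 replicates for
  sampler-versus-oracle agreement — sizes chosen so Monte-Carlo error is
  well below the asserted tolerances.
* Exact enumeration budget: $10^7$ arrangements by default, raisable per
  call.
* Degenerate inputs (zero-variance profiles or genes, empty families,
  missing labels, negative ratios) fail fast with messages naming the
  offending sample, gene or family.

## Known limitations

* The aggregation statistic ignores *which* subtype aggregates and does
  not grade concordance beyond "two or more"; a family of three identical
  tumors counts once.
* The test conditions on the observed label multiset; it has no notion of
  population subtype frequencies beyond the sample.
* Conservatism at conventional levels is inherent to the discrete
  statistic (see above).
* The synthetic generator's Gaussian, gene-independent noise understates
  the difficulty of real-array classification; recovery rates on
  synthetic cohorts are upper bounds.
* Signature classifiers are only as good as their supplied weights; the
  training convenience is not a substitute for a properly validated
  published signature.
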