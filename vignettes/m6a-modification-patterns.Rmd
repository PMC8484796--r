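---
title: "Discovering m6A modification patterns and the m6A score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering m6A modification patterns and the m6A score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6ascape)
```

# Overview

`m6ascape` implements a complete analysis chain for expression-defined
molecular subtyping of tumor cohorts on the 21-gene m6A regulator panel:
cohort merging with batch adjustment, resampling consensus clustering,
single-sample gene-set scoring, derivation of a prognostic per-sample m6A
score, and the survival and association statistics that compare the
resulting groups. This vignette documents the models, their assumptions,
the tunable parameters and the design decisions, so that results can be
interpreted — and the limits of what the test suite demonstrates can be
judged — without reading the source.

# Input model and preprocessing

Expression is a genes x samples real matrix assumed to be on log2 scale;
`read_expression(..., log2_offset = TRUE)` applies `log2(x + 1)` for raw
counts or TPM. Missing or non-finite values are a hard error: none of the
downstream steps (distances, running-sum enrichment, Cox regression) has a
principled way to impute, so silent filling is refused. Clinical tables
carry per-sample overall-survival time (days), a 0/1 event indicator and
arbitrary covariate columns; sample ids are harmonized across inputs by
intersection, with dropped ids reported and ordering taken from the
expression matrix.

## Batch adjustment

Multi-cohort matrices are merged on the gene intersection and adjusted by a
parametric empirical-Bayes location/scale model. Per gene the data are
standardized by the batch-size-weighted grand mean and pooled residual
variance; per-batch per-gene location and scale estimates are then shrunk
toward batch-wide priors — Normal for location, inverse-gamma for scale,
both with method-of-moments hyperparameters — by iterating the posterior
updates to convergence (max absolute change `< 1e-6`, cap 100 iterations)
and back-transforming. No reference batch is used and no biological
covariates enter the model: correction runs before clustering, when the
subtype labels are still unknown, so protecting them is impossible and
pretending otherwise would leak information.

Two properties of EB shrinkage are worth stating explicitly. First, the
*shared* component of a batch effect (the part common to all genes) is
removed essentially completely, but per-gene deviations around it are only
partially removed — by design, since at realistic batch sizes those
deviations are dominated by sampling noise. Tests therefore verify exact
mean equalization only for the non-shrunk variant (`eb = FALSE`, which
removes the observed per-batch location and scale outright) and verify for
the EB default that the shared shift is gone, that the residual per-gene
gap is within the sampling-noise envelope, and that output matches the
reference implementation in the `sva` package closely. Second, the
adjustment is only approximately idempotent: a second pass re-estimates
(small) batch means and shrinks again, moving values at the
sampling-noise scale (tested at 0.05 RMS), not at numerical precision.

# Consensus clustering

Modification patterns are found by resampling consensus clustering of
samples on the regulator panel. Each repetition draws `ceiling(0.8 n)`
samples without replacement, clusters them by agglomerative Ward linkage on
Euclidean distance, and cuts at each candidate k; the consensus matrix
entry for a pair of samples is its co-clustering count divided by its
co-sampling count. Final labels per k come from average-linkage clustering
of `1 - M`. Defaults: 1,000 repetitions (the demo configuration uses 100,
which on separable data changes consensus entries by well under 0.1),
subsample fraction 0.8, genes z-scored before distances so that scale
differences across the panel do not dominate. The base clusterer, linkage
and scaling are configurable.

k is chosen by minimizing PAC, the proportion of ambiguous consensus
entries in (0.1, 0.9), with ties going to the smaller k and the
consensus-CDF delta-area reported as a secondary diagnostic. If even the
best PAC exceeds 0.5 the result is flagged unstable. PAC has a known
failure mode at k well above the truth — most entries fall below the 0.1
ambiguity floor and PAC drops again — which is why the flag, not the argmin
alone, should be consulted on weakly structured data. For two-cluster
results, cluster "A" is oriented to the better-survival arm (higher
Kaplan-Meier median) when clinical data are available, matching the usual
presentation; otherwise A is the larger cluster.

PCA (gene-centered SVD, components signed so the largest-magnitude loading
is positive) provides the standard visual check that the partition
separates samples.

# Single-sample enrichment

The default scorer is ssGSEA: per sample, genes are ranked by expression
(average ranks on ties); the enrichment score is the sum over ranked
positions of the difference between the weighted in-set running ECDF
(weights `|rank|^alpha`, default `alpha = 0.25`) and the unweighted
out-of-set running ECDF. At `alpha = 0` the score depends only on ranks, is
invariant to monotone transforms of a sample's values, and the score of a
set and of its complement sum to zero — all tested, along with exact
agreement (1e-12) with a brute-force positional-loop oracle. A GSVA-style
variant is provided (per-gene Gaussian-kernel CDF across samples, bandwidth
SD/4, symmetric-rank weights, signed maximum deviation of the random walk);
ssGSEA is the default for both immune-cell and pathway scoring because its
definition is simpler and its oracle exact. Pathway over-representation of
DEG lists uses the upper-tail hypergeometric test with BH adjustment.

The 24-immune-cell signature collection is an input GMT, not shipped: its
gene lists are not part of this package's sources, and tests use synthetic
set collections with planted activations instead.

# The m6A score

The signature derivation chains five steps, each exposed as a function:

1. **Moderated differential expression** between the two patterns: a
   per-gene two-group linear model with empirical-Bayes variance shrinkage
   — posterior variance `(d0 s0^2 + dg sg^2)/(d0 + dg)` with `d0`, `s0^2`
   fitted by moments on `log sg^2` (via `limma::squeezeVar`), moderated t
   on `d0 + dg` degrees of freedom. `prior_df = 0` gives the textbook
   pooled t (equality tested to 1e-10); the EB route matches
   `limma::eBayes` numerically.
2. **DEG thresholds**: adjusted p `< 0.05` and `|log2FC| > 0.5`, both
   strict, as is conventional for these cutoffs.
3. **Random-forest redundancy removal**: a classifier of the cluster
   labels; importance is out-of-bag permutation mean decrease in accuracy,
   and the default keep rule retains genes with positive importance. Note
   that permutation importance does not eliminate correlated duplicates —
   both copies of an informative gene keep positive importance (tested);
   "redundancy removal" here means discarding genes that contribute
   nothing, not enforcing orthogonality.
4. **Univariate Cox filter** on continuous expression, keeping genes with
   Wald p `< 0.05`. Continuous (not dichotomized) expression is used: it is
   the stronger convention and requires no extra cutpoint parameter.
5. **Sign partition and score**: X = genes with positive Cox coefficient,
   Y = negative; a coefficient of exactly zero is treated as an error (a
   measure-zero event signalling degenerate input, not a case to assign
   arbitrarily). The per-sample raw score is `sum(X rows) - sum(Y rows)` on
   the expression values as given (a config flag enables per-gene
   standardization first); scores are z-scaled with the training cohort's
   mean and n-1 SD, which are stored in the model together with the median
   so that the signature can be applied unchanged to new cohorts. Samples
   strictly above the median are "high"; ties go to "low"
   (deterministic).

An optional PCA mode (score = PC1 projection of the signature genes) is
available for comparison, but the explicit X/Y sum is the primary
definition: it is the formula form of the score, transparent about each
gene's direction of effect.

# Statistical back-end

Cox models are fit by `survival::coxph` with Efron tie handling (more
accurate than Breslow; equality when no ties is tested), Wald 95% CIs
`exp(beta ± 1.96 SE)` and Wald p-values. Kaplan-Meier and log-rank come
from `survfit`/`survdiff`; Wilcoxon rank-sum from `wilcox.test` (exact for
small tie-free samples, normal approximation with corrections otherwise);
Fisher's exact p from the conditional two-sided convention, with the sample
odds ratio `ad/bc` as the effect summary; multiple testing is BH
throughout (configurable to Bonferroni); AUC is the Mann-Whitney statistic
`U/(n1 n0)` with ties counted 1/2. All two-sided, matching the standard
star conventions (`*` < 0.05 through `****` < 0.0001, applied to adjusted
p-values as the conservative default).

For immunotherapy-response ROC analyses the responder label is defined as
TIDE score `< 0` on the externally computed TIDE column (the package
consumes TIDE and IC50 values; it does not compute them), with the
threshold configurable.

# The synthetic-cohort generator

`simulate_cohort()` generates the structure every downstream stage assumes:
two latent clusters (membership Bernoulli, default proportion 0.5) with a
mean shift (default 2 SD) on the regulator panel; background genes N(0,1);
configurable signature sets shifted per cluster; per-cohort location/scale
batch effects; exponential proportional-hazards survival with the cluster
as planted log hazard ratio (default log 2) and administrative-uniform
censoring on `[0, c_max]`, with `c_max` solved numerically for the target
censoring fraction (default 30%); Bernoulli per-gene mutations at
group-specific frequencies. The default baseline hazard 0.001/day puts
median survival near 700 days, a realistic order for pancreatic-cancer
cohorts. One global seed expands into fixed per-component substreams, so a
cohort is bit-reproducible and each component is independently
reproducible.

What the generator does *not* emulate: negative-binomial count noise,
library-size variation, gene-gene correlation beyond the planted block
structure, segment-level copy number, or informative censoring. Passing
tests on this generator therefore demonstrate that the algorithms recover
the structure they model — planted clusters (ARI ≥ 0.95 at 2 SD and
n = 200), planted hazard ratios (log-HR recovered within [0.55, 0.85] at
n = 2,000), calibrated type-I error (within [0.03, 0.07] at nominal 0.05
over 500 null replicates per test) — not that real RNA-seq cohorts meet
those model assumptions.

# Numerical choices and degenerate inputs

Problem sizes in the test suite are chosen so the full suite runs in a few
minutes on one CPU: 100 consensus repetitions where the analysis default is
1,000 (drift of consensus entries between the two is under 0.1 on separable
data, which is tested), 200-300 trees in test forests, 500-replicate null
calibrations. Geometry-oracle clustering tests (planted point clouds whose
separation lives on one or two genes) disable per-gene z-scoring, which
would otherwise shrink exactly the planted dimension; three-cluster
fixtures use an equilateral layout so the k = 2 merge is intrinsically
ambiguous and model selection is a fair test at every seed.

Degenerate inputs are errors, not silent repairs: zero-variance genes in
batch adjustment or correlation, single-sample batches, constant raw
scores, a single class for the random forest, k ≥ n for clustering, sample
pairs never co-sampled (advice: more repetitions), perfect separation in
Cox fits. Warnings mark recoverable oddities: unmapped MAF classification
terms (mapped to `other`), duplicated genes within a GMT line
(deduplicated), gene sets with no genes in the matrix (skipped), all-equal
scores at the median split (everything "low").

# Known limitations

The pipeline assumes two-pattern structure for cluster naming and for the
signature contrast (more clusters are clustered and labelled, but the
score derivation contrasts two groups); proportional hazards is assumed
wherever Cox models appear; the mutation-frequency denominator is all
assayed samples; CNV analysis is gene-level call counting, not segment or
peak detection; and figures are out of scope — outputs are tabular (TSV +
JSON manifest) by design.
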