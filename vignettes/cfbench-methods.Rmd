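---
title: "Benchmarking composite-feature outcome classifiers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking composite-feature outcome classifiers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Outcome prediction from tumor gene expression is usually framed as a
two-class problem: did the patient suffer an event (distant metastasis or
death) within five years — *poor* outcome, labelled 1 — or not (*good*,
labelled 0). A recurring proposal in the field is to replace single-gene
features with *composite features*: aggregates of several genes' expression,
where a secondary data source (a protein--protein interaction network, a
pathway database, a curated gene-set collection) guides which genes are
aggregated. `cfbench` implements four feature-extraction methods, three
classifiers and a strictly leakage-free cross-dataset evaluation protocol so
that the claimed advantages of composite features — higher accuracy, more
stable signatures — can be tested under identical conditions, together with
a synthetic multi-cohort generator that provides ground truth.

# Data model and normalization

An `ExpressionDataset` is a samples-by-genes matrix with a binary outcome
label and an optional binary ER (estrogen receptor) status per sample. All
methods operate on per-gene z-normalized data: each gene column is centred
and scaled to unit standard deviation *within a dataset*. We use the sample
standard deviation (n−1 denominator) throughout — for z-normalization and
inside every t-statistic; the choice is a convention and only rescales
statistics by a common factor. Merging cohorts (for the merged and
ER-stratified settings) row-concatenates the matrices and then re-normalizes
the pooled matrix, so train-time normalization never sees test data. In the
ER-stratified setting the ER-positive filter is applied *before* pooling and
normalization.

Secondary sources are restricted to the measured gene universe before any
search, mirroring the practice of discarding network proteins without
expression data.

# The four feature extractors

**Single genes (SG).** Every gene is a feature scored by the absolute Welch
t-statistic between the classes,
$t = (\mu_1 - \mu_0) / \sqrt{s_1^2/k_1 + s_0^2/k_0}$, positive when the
poor-outcome mean is higher. Ties are broken lexicographically by gene id so
rankings are reproducible.

**Subnetwork markers (mutual-information greedy search).** The activity of a
gene set $S$ in sample $i$ is $a_i = \sum_{j \in S} e_{ij} / \sqrt{|S|}$.
The $\sqrt{|S|}$ normalizer (rather than the plain mean, which is available
via `normalizer = "mean"`) keeps the per-feature variance near 1 on
z-scored data; note that the mutual-information criterion below is invariant
to this choice because equal-width binning is invariant under positive
scaling. Activities are discretized into $\lfloor \log_2 k \rfloor + 1$
equal-width bins spanning the observed range ($k$ = number of samples), and
the score is the mutual information (in bits) between bin index and class
label. Every measured network gene seeds one greedy search: the neighbor
(within 2 hops of the seed by default) whose addition maximizes MI is added
while MI strictly increases; equal gains are resolved towards the
lexicographically smallest gene, which makes the search deterministic and
independent of node order. Identical gene sets found from different seeds
are deduplicated. A significance filter then keeps only subnetworks whose
MI exceeds the 95th percentile of three permutation nulls: random connected
subnetworks of the same size, random gene sets of the same size (gene-to-
node permutation), and label permutations.

A caveat the package makes explicit: because the greedy search maximizes MI
*before* the filter is applied, the filter is anti-conservative on
searched features — on pure-noise data a third or more of greedy-grown
subnetworks can pass all three tests, since the nulls are not themselves
maximized. The filter is well calibrated for features that were not
produced by the maximizing search (the suite verifies a ≈5% pass rate for
randomly grown connected subnetworks on null data). This selection bias is
inherent to the published construction; re-running the full search inside
every permutation would remove it at roughly a thousandfold cost.

**CORG pathway features.** For each gene set, genes are ordered by
t-statistic — descending if the gene with the largest |t| has positive t,
ascending otherwise — and the prefix is extended greedily while the
t-statistic of the prefix's averaged activity strictly increases in absolute
value. The feature's members are the resulting condition-responsive genes
(CORGs) and its score the final $|t|$. Because the t-statistic is scale
invariant, the activity normalizer is irrelevant here. Collections larger
than 400 sets are truncated to the 400 best-scoring ones by default.

**Hub correlation-difference features.** Candidate hubs are the 15% most
densely connected network nodes (ties at the cutoff included), determined on
the full network *before* expression filtering. For each measured candidate,
the hub difference of an edge is the Pearson correlation of hub and
interactor within the poor class minus the same correlation within the good
class; the average over the hub's measured neighbors is compared to a
label-permutation null (1000 permutations by default), and hubs with
empirical $p < 0.05$ are kept, ranked by absolute average difference. Each
kept hub contributes one classifier dimension per edge: the per-sample
difference between hub and interactor expression. Degenerate within-class
correlations (zero variance) contribute 0 with a warning; classes need at
least 3 samples for correlations to be meaningful.

# Classifiers

The nearest-mean classifier projects a sample onto the line connecting the
two class means and scores it by the distance to the good mean minus the
distance to the poor mean (positive = poor-like; an exact tie is classified
good, a deterministic documented convention). The weighted 3-nearest-
neighbour classifier scores by the label vote of the three nearest training
samples under normalized inverse-distance weights; a zero-distance neighbor
takes the whole weight (split equally if several coincide). Logistic
regression is fitted by iteratively reweighted least squares with a small L2
ridge ($\lambda = 10^{-4}$) on the non-intercept weights; with
$\lambda = 0$ the fit reproduces the well-known divergence on wide matrices
(hundreds of features, tens of samples) and the classifier is flagged
`converged = FALSE` so evaluation summaries can exclude it. Performance is
always the Mann--Whitney AUC — the probability that a poor sample outscores
a good one, ties counting one half.

# The evaluation protocol

All training decisions are taken on the training cohort alone. The number
of features is chosen by stratified 5-fold cross-validation *inside* the
training set: features are re-extracted on each fold's 4/5 training part,
classifiers are trained over the feature-count grid (all integers up to 400
by default; for hub features the grid counts feature *sets*, since a hub's
edges are not individually ranked), and the count with the best mean
held-out AUC wins, ties towards fewer features. Fold assignment is seeded
from a content hash of the training data taken in canonical sample order,
so results are reproducible and independent of row order. The final model
re-extracts features and trains on the full training cohort and is scored
exactly once on the untouched test cohort. Fixed-feature-count policies
(`fixed_50`, `fixed_100`, `fixed_150`, or any `fixed_k`) replace the inner
CV; when fewer features exist than requested the pair is recorded as
infeasible rather than silently truncated.

Three settings: *paired* (every ordered cohort pair; D cohorts give
D(D−1) records), *merged* (leave one cohort out, pool and renormalize the
rest; D records) and *ER-stratified merged* (restrict to ER-positive cases
first; D records, infeasible cohorts flagged). Method comparisons use
paired Wilcoxon signed-rank tests over matched (train, test) pairs — exact
null up to 25 non-zero differences, normal approximation with continuity
correction beyond, zero differences dropped, all-zero series giving p = 1 —
with Bonferroni correction over the comparison family. Win/loss summaries
report $\log_2((\text{wins}+1)/(\text{losses}+1))$ per combination pair,
the +1 smoothing keeping the matrix finite under clean sweeps.

# Randomization of secondary data

`permute_identities()` applies one uniform random bijection over a source's
own gene universe (including unmeasured proteins, so the measured/unmeasured
mixture is itself shuffled; a `universe` argument restricts the domain when
wanted). Topology — degree sequence, set sizes — is exactly preserved while
all biological meaning is destroyed. `randomization_experiment()` re-runs
the full paired evaluation on the real source and on each of n randomized
instances (drawn independently per instance) and tests, one-sidedly per
instance with Bonferroni correction, whether the real source outperforms.

# The synthetic benchmark

The generator emulates the structure of the real multi-cohort benchmarks:
several cohorts share one set of outcome-associated genes; each cohort has
its own per-gene additive batch offset (sd 0.3 by default); classes are
imbalanced (30% poor by default, within the 20–35% range of the clinical
cohorts); cohorts are z-normalized after generation; ER status is drawn
independently with probability 0.7 (a coupling switch lowers the ER-positive
rate among poor-outcome samples to emulate subtype heterogeneity).
Informative genes gain an additive mean shift (in background-sd units) in
poor samples — the simplest mechanism matching t-statistic-based extractors.
Members of each planted module share a latent factor with loading 0.5 so
that module genes are correlated and hub statistics are non-trivial (under
independent genes every correlation difference is identically zero). In the
designated flip module the factor's sign follows the class for the non-hub
members, so hub--member correlations are positive in good and negative in
poor samples — the signal the hub extractor is designed to find. The
network is a static-fitness power-law graph (exponent 2.5, mean degree 4)
over the measured genes plus 10% unmeasured protein nodes; each planted
module is wired into a connected induced subgraph (star around the module
hub plus a path), and the flip module's hub receives a few extra random
edges so it ranks among the densely connected candidates. Gene-set
collections contain one planted set per module plus uniform random sets.

What the generator does *not* emulate: platform differences beyond additive
offsets, probe-level noise, missing values, correlated background genes, or
realistic pathway size distributions. Passing tests on this generator show
that the algorithms and protocol behave as specified under a known ground
truth — not that any method will perform comparably on clinical data.

## Problem sizes and power

The suite and the acceptance script run the protocol at deliberately small
sizes chosen so each property is measured with adequate power: protocol
counts on six cohorts of 24 samples; null calibration on five cohorts of 50
samples (20 ordered pairs); recovery experiments at 100 samples per cohort
with effect size 2 for mean-shift recovery and a size-14 flip module for
hub recovery (a design-stage power probe across twelve generator seeds
showed the hub's permutation p-value below 0.05 at every seed with this
geometry — the flip signal dilutes with every non-flipping neighbor, so
very small flip modules are underpowered); the real-versus-random
experiment uses four cohorts of 50 samples, ten randomized instances and
ten-fold Bonferroni correction, with twelve matched pairs per instance so
that the smallest attainable one-sided signed-rank p-value (1/4096) can
survive the correction. Permutation counts are reduced (60–500) where only
a 0.05-level decision is needed.

# Numerical conventions and degenerate inputs

Constant gene columns are an error in `znormalize()` (named in the
message); constant activity vectors have MI 0 by the single-occupied-bin
convention; zero-variance correlations contribute 0 with a warning; a
two-group t-statistic with both group variances zero is an error; AUC
requires both classes. Score ties in ranked lists are always resolved
lexicographically by feature name. All randomness flows through explicit
seeds or content-derived seeds, and `extract_features()` memoises on a
fingerprint of its inputs — extraction is a pure function of training data,
secondary source and parameters, so caching cannot leak test information.

# Known limitations

The significance filter's anti-conservativeness on searched subnetworks
(above) is the largest caveat; results based on "number of significant
subnetworks" should not be read as FDR-controlled. The 3NN weight formula
and the activity normalizer follow common conventions where the original
descriptions are ambiguous; both are configurable. The Jaccard stability
correction uses a transparent sampling null (matched-size random signature
pairs from the selection universe) rather than any particular published
sampling scheme. The exact win/loss transform is a smoothed log-ratio of
our own choosing.
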