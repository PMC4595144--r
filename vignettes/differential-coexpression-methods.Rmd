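---
title: "Methods: case-control differential co-expression analysis with dcoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control differential co-expression analysis with dcoex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcoex)
```

# Scope and model

`dcoex` implements a complete case-control analysis of blood microarray
expression profiles, of the kind used to ask whether a past disease event
(here, a history of aneurysmal subarachnoid hemorrhage from a ruptured
intracranial aneurysm) leaves a detectable trace in the peripheral blood
transcriptome. The package covers six analysis layers — quality control,
surrogate-variable adjustment, differential expression, co-expression
modules, differential co-expression, and classification — plus a
synthetic-data generator that plants known structure so that every layer
can be validated against ground truth.

## Quality control

Sample QC applies, in a fixed order: laboratory filters (RNA integrity
number strictly below 6, 260/280 ratio strictly below 1.8), principal
component outliers, a sex-concordance check, and duplicate removal.
Later steps operate on the survivors of earlier steps, so an outlier
cannot also be reported as a duplicate. Rerunning QC on cleaned data
excludes nothing further.

Two places where the procedure is necessarily a design choice of this
package:

* **PC outliers.** Visual inspection of PC plots is not reproducible, so
  the rule used here is numeric: a sample is an outlier when its PC1 or
  PC2 score deviates from the component median by more than `k_mad = 5`
  robust standard deviations. The robust SD is the larger of the scaled
  median absolute deviation (factor 1.4826) and a decile-range estimate
  `(q90 - q10)/2.563`; both equal the SD under normality. The decile
  guard exists because PC scores are often *multimodal* — chip batches
  form legitimate clusters on a PC — and the raw MAD, anchored in the
  majority cluster, would then flag an entire minority batch as
  "outliers". The decile range spans the clusters, so only samples far
  outside all of them are flagged; a handful of gross failures cannot
  inflate either estimate. The multiplier is configurable; 5 robust SDs
  flags only failures an analyst would also flag by eye.
* **Sex check.** Per sex-marker transcript, samples are split by an exact
  one-dimensional two-means clustering; the threshold is the midpoint of
  the two cluster means, and the side of the split is oriented by
  majority agreement with the reported sex. A sample is excluded when at
  least two of the (by default eight) marker probes contradict its
  reported sex — one discordant probe is treated as probe-level noise.

Probe QC removes non-specific probes, non-autosomal probes (chromosomes
X, Y, MT) and probes mapping to retired transcripts; a probe matching
several rules is reported once, in that priority order (the order only
affects bookkeeping, not the retained set). Quantile normalization is
performed on the raw scale (via `limma::normalizeQuantiles`) and followed
by log2. The order is immaterial for every rank-based downstream step,
since log2 is monotone; it matters only for the scale on which the
logistic regressions see the data, and normalize-then-log is the
convention for raw array intensities.

Duplicate pairs (Pearson correlation > 0.99) keep the earlier column —
an arbitrary but deterministic tie-break.

## Surrogate variables

Unmodelled heterogeneity (chip batches, cell-composition drift) is
estimated by a deterministic two-step procedure: per probe, expression is
regressed on the protected primary variable (case status) and the top
right-singular vectors of the residual matrix are taken as surrogate
variables. Protecting case status in step one prevents the surrogate
variables from absorbing the disease signal. With `n_sv = "auto"` the
dimension is chosen by parallel analysis: a component is kept while its
variance share exceeds the 95th percentile of the matching component's
share across 20 row-wise permutations of the residuals. The number of
surrogate variables can equally be fixed (`n_sv = 14` reproduces a
fixed-dimension adjustment); whether a fixed count or the automatic
criterion is preferable is a judgement call we surface as an option
rather than hard-code.

## Differential expression

Per probe, a logistic regression of case status on standardized probe
expression plus the surrogate variables; the Wald z test for the
expression coefficient is reported. The Wald test (rather than a
likelihood-ratio test) is the standard choice for array-scale scans: one
fit per probe instead of two. Probes with non-converged or separated fits
(fitted probabilities collapsing to 0/1) are flagged and assigned p = 1 —
a deliberately conservative fallback that can only cost power, never
inflate the false-positive rate. Standardizing expression only rescales
the coefficient (to log-odds per expression SD); p-values are unchanged.

Multiple testing uses Benjamini-Hochberg FDR. The two-stage design
selects discovery probes at FDR < 0.05, refits exactly those in the
replication set, and re-applies BH *within the selected set* — the
conventional reading of a two-stage replication design. Candidate-gene
lookup restricts to probes mapping to a supplied gene list and applies a
Bonferroni threshold of 0.05 over the number of candidate probes tested.

## Co-expression and the CDC test

The adjacency is `|rho|^beta` with Spearman correlations (midranks for
ties), robust to the influential outliers that Pearson correlation is
leveraged by on array data. Defaults: unsigned network, soft power
`beta = 6` — the conventional unsigned default; both are configurable.
Modules come from average-linkage clustering of `1 - adjacency` with a
static cut at height 0.96 and a minimum module size of 30; no
topological-overlap transformation is applied, and no dynamic tree-cut:
the clustering operates on the co-expression matrix directly. Module
labels follow the familiar size-ordered colour palette (turquoise, blue,
brown, ...).

The co-differential co-expression (CDC) test asks whether a module's
mean gene significance `GS = -log10(p)` from the differential-expression
scan is higher than chance. The null resamples random gene sets of the
same size from all genes in the assignment universe (any label,
including unassigned): the hypothesis is about the module's genes
relative to all genes, so the exchangeable unit is the gene, not the
sample. `p_perm = (r + 1)/(n_perm + 1)` with `r` the count of null means
at or above the observed mean, which keeps the p-value strictly positive.

## Differential co-expression

Per group (cases, controls) the signed-powered correlation is
`c = sign(rho) |rho|^beta`; the change score is
`d_ij = sqrt(0.5 |c_case - c_control|)`, which lies in [0, 1] and reaches
1 only when a perfect positive correlation flips to a perfect negative
one. Modules of co-changing genes are extracted from `1 - d` with the
same clustering machinery; their colour labels are assigned in seeded
random order, reflecting the convention that differential-co-expression
module colours carry no size meaning.

The dispersion statistic of a module is the root-mean-square change over
its unordered gene pairs, `D_s = sqrt(mean d_ij^2)`. Inference permutes
case/control labels (preserving group sizes), keeping module membership
fixed: recomputing the clustering inside every permutation would answer a
different question (about the pipeline, not about the observed modules)
and is computationally prohibitive at 10 000 permutations. The
permutation index is the count of null statistics at or above the
observed one, `p_emp = index / n_perm`, Bonferroni-corrected by the
number of modules tested. For very small groups the test can enumerate
all label splits exactly (`exhaustive = TRUE`).

## Module preservation

Preservation of a module between discovery and replication is summarized
by two statistics rather than the full seven-statistic battery: a
*density* statistic (mean within-module edge weight of the module's
network in the replication data) and a *connectivity* statistic
(correlation of the genes' intramodular connectivity between discovery
and replication). Each is standardized against a null of random same-size
gene sets drawn in the replication data (200 draws by default), and the
Z-summary is the mean of the two Z scores, with strong preservation
declared above 10. The null resamples within the replication set only —
the question is whether the module looks special *there*. Two
consequences worth knowing: for a homogeneous planted module (equal
factor loadings, hence no hub structure) the connectivity statistic is
uninformative and preservation is carried by density; and when a strong
module occupies a large fraction of the gene universe, random null sets
are contaminated by its genes, which is why validation uses modules that
are a small fraction (about 5%) of the universe, as on a real array.

## Hub genes

Within a module, an unweighted graph keeps the within-module edges at or
above the 0.9 quantile of the module's edge weights (boundary ties kept,
so uniform-weight modules stay connected), pruned to the largest
connected component. Binarizing, rather than carrying weights into the
metrics, makes the four criteria directly comparable across modules.
Per node: degree, unnormalized betweenness, mean shortest-path length,
and the local clustering coefficient (defined as 0 for degree < 2 so
"lowest clustering" is well-defined). A gene scores one point for each
of: top 20% degree, top 20% betweenness, bottom 20% path length, bottom
20% clustering coefficient — boundary ties inclusive, so no node is
excluded by arbitrary ordering — and is a hub at score >= 2. In the full
pipeline, hub analysis runs only on modules that pass both the
permutation gate (p_bonf < 0.05) and the preservation gate
(Z-summary > 10).

## Nearest shrunken centroid classification

The classifier standardizes each gene's class-centroid difference,
`d_ik = (class mean - overall mean) / (m_k (s_i + s0))` with
`m_k = sqrt(1/n_k - 1/n)` and the fudge constant `s0` set to the median
pooled SD (the method's standard stabilizer for near-constant genes),
soft-thresholds it by `delta`, and reconstructs shrunken centroids.
Genes whose differences shrink to zero drop out of the classifier. The
delta grid is 30 linear values from 0 to the largest `|d_ik|`;
cross-validation (stratified 10-fold) picks the *largest* delta at the
minimal error, preferring smaller gene sets at equal accuracy. Ties
between classes at equal discriminant predict control. A
smallest-gene-set report scans the grid from most to least shrunken and
returns the first active set meeting a replication misclassification
ceiling. Replication misclassification is the sole selection metric for
that report; no classifier-level FDR estimate is computed.

# The synthetic-data generator

`generate_dataset()` emulates an Illumina HumanHT-12-style case-control
study. Defaults are the study design the pipeline targets: 119 cases and
118 controls before QC, log2 intensities around a baseline of 7
(SD 0.6) with probe noise SD 1, four chip batches (per-probe batch
offsets, SD 0.3), eight tightly bimodal sex-marker probes (shift 3 log2
units in males, reduced residual noise as on real arrays), two planted
duplicates (near-copies, correlation > 0.99), nine PC outliers
(mean-shifted by 10 noise SDs) and eight low-RIN samples. Metadata
frequencies (sex, hypertension, smoking, familial-aneurysm status, age)
roughly match the baseline table of a post-hemorrhage case-control
cohort; leukocyte differential counts are drawn identically in both
groups. The default probe count is 34 135 — the post-QC scale of the
HT-12 array — but validation runs use 300-2000 probes, which exercises
every code path at a fraction of the cost; the methods are scale-free in
the probe dimension apart from the gene-universe caveat for preservation
nulls noted above.

Planted co-expression modules follow a single-factor model:
`z = sqrt(r) f + sqrt(1 - r) e` (scaled by the noise SD), so the expected
pairwise correlation within a group equals the target `r`. The factor is
standardized to unit sample variance, which removes the realized-variance
jitter that would otherwise move whole-module correlations by several
hundredths. A loss of co-expression in cases is planted by zeroing the
case-group loading — matching the "loss of co-regulation" interpretation
of differential co-expression — rather than by an anti-correlated factor.
Negative correlation targets are realised with sign-alternating loadings
(exact negative equicorrelation is not positive definite beyond two
genes). A module with `preserved_in_replication = FALSE` receives its
factor only in the generator's suggested discovery subset
(`metadata$set_suggested`), so a split honouring that suggestion sees the
module dissolve in replication.

What the generator does *not* emulate: bead-level array artifacts, probe
sequences, heavy-tailed intensity distributions, correlated noise between
modules, and cell-composition confounding beyond generic batch effects.
Passing tests therefore demonstrate that the statistics recover the
structures they are defined on — not that real blood data satisfies the
factor-model assumptions.

# Numerical choices and degenerate inputs

* Constant genes have undefined rank correlations; they are set to 0 with
  a warning rather than propagating NAs into the clustering.
* `p_emp` from the dispersion test may be exactly 0 (the observed
  statistic exceeded every permutation); the CDC test, whose null is
  resampled rather than enumerated, uses the `(r + 1)/(n_perm + 1)` form
  and stays positive.
* All randomized steps (generator, splits, permutation nulls, CV folds,
  colour shuffles) take explicit seeds; the pipeline derives per-stage
  seeds deterministically from one global seed, so stages rerun in
  isolation reproduce their in-pipeline results.
* Validation problem sizes: module-level tests use 300-1000 probes and
  70 samples per group; permutation tests use 200-1000 permutations in
  unit tests and 10 000 in the pipeline default, matching the design the
  dispersion test was defined with.

# Known limitations

* The PC-outlier rule is a reproducible surrogate for visual inspection;
  on real data the two will not flag identical sample sets.
* The two-statistic Z-summary is a deliberate reduction of the full
  preservation battery; it captures density and connectivity, not
  separability or cross-tabulation statistics.
* The logistic scan treats probes independently; no moderated variance or
  empirical-Bayes shrinkage is applied.
* Two-class classification only; the shrunken-centroid machinery extends
  to more classes, but nothing in this pipeline needs it.
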