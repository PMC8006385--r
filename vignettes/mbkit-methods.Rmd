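---
title: "Models and methods in mbkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mbkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mbkit)
```

This vignette documents the statistical models behind each mbkit module,
the parameters that matter, the numerical and design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate. Everything quantitative asserted here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The container and its invariants

A `MicrobiomeExperiment` couples a features × samples matrix of raw read
counts, an optional taxonomy table, and a samples × covariates metadata
table. It extends `SummarizedExperiment`, so taxonomy lives in `rowData()`
and metadata in `colData()`, and any subsetting keeps the three tables
aligned by construction; the class validity re-checks alignment, uniqueness
of identifiers, and that counts are non-negative and integral.

Two conventions are fixed here because downstream behavior depends on them:

* **Empty selections are errors**, not empty objects. Diversity, GLMs and
  cross-validation are all undefined on zero samples or features, so
  `pickSamples()`/`pickFeatures()` refuse to produce them.
* **Covariate typing** is deterministic: a metadata column is *continuous*
  iff it is numeric with more than 8 distinct values, otherwise
  *categorical*. A rule this blunt is wrong for some columns (an integer
  score with 9 levels becomes continuous), but any automatic plot/test
  dispatch needs a reproducible rule; the cut at 8 keeps small Likert-type
  scales categorical.
* Missing taxonomy entries are the explicit string `"unclassified"` —
  never `NA` or `""` — so aggregation at a rank with missing labels
  produces a visible `"unclassified"` bucket rather than silently dropping
  reads.

## Abundance scales

Three assays are derived from one stored count matrix:

* *relative abundance*: column proportions (each sample sums to 1);
* *logCPM*: `log2(c · 10⁶ / L + 1)` with `L` the sample's library size.
  The +1 pseudocount maps zeros to exactly 0 and makes the transform
  invariant to rescaling a sample's counts; the base-2 log makes
  differences directly interpretable as log2 fold changes. The pseudocount
  convention was an open choice; `log2(CPM + 1)` was fixed because the
  zero-maps-to-zero property is what the filters and the moderated-t path
  rely on.

Taxonomy aggregation (`upsampleCounts()`) sums counts of features sharing a
label at the requested rank, in integer arithmetic, so per-sample totals
are conserved exactly. Within an aggregated group a coarser rank is kept
only when unanimous; disagreeing lineages collapse to `"unclassified"`.

Feature filtering conjoins (AND) three criteria — mean raw count, mean
relative abundance, prevalence — plus an explicit discard list. The
pipeline order is fixed: sample filters first, then feature criteria
evaluated on the retained samples, because prevalence depends on the sample
set and an unordered definition would not be reproducible. Relative-
abundance filtering uses the per-feature *mean* across samples (the
per-sample alternative was rejected as it conflates prevalence with
abundance). Threshold-only filtering is idempotent.

Continuous covariates are discretized by quantile bins by default (robust
to skewed covariates like library size or age in clinical cohorts), with
equal-width bins and verbatim breakpoints available. Bins are `[lo, hi)`
with the last bin closed.

## Diversity

Alpha diversity works on per-sample proportions: Shannon entropy (natural
log; zero-proportion terms contribute 0), Gini-Simpson, inverse Simpson,
and richness (count of nonzero features). The implementations are direct
transcriptions of the formulas; tests check the closed forms on uniform
communities and the bounds `shannon ≤ ln(richness)` and
`inverse_simpson ≤ richness`.

Group tests delegate to base R (`wilcox.test`, `t.test` with Welch's
correction, `kruskal.test`). The Wilcoxon switches to exact enumeration
when both groups have at most 8 samples and no ties; otherwise the
tie-corrected normal approximation with continuity correction applies.

Beta diversity supports Bray-Curtis and the binary (presence/absence)
Jaccard index. Bray-Curtis is computed on **relative abundances by
default**: on raw counts it is dominated by library-size differences,
which are sequencing artifacts rather than community structure; a
raw-count option remains for deliberately library-aware analyses. Jaccard
always binarizes the raw counts. Bray-Curtis does not satisfy the triangle
inequality in general, so no test asserts it; symmetry, zero diagonal and
the [0, 1] range are enforced by the `DistanceMatrix` validity.

### PERMANOVA

For `a` groups and `N` samples with distance matrix `d`:

* `SS_T = (1/N) Σ_{i<j} d_ij²`
* `SS_W = Σ_g (1/n_g) Σ_{i<j∈g} d_ij²`
* `F = ((SS_T − SS_W)/(a−1)) / (SS_W/(N−a))`

The p value comes from label permutations with the `(1 + b)/(1 + m)`
estimator, which can never return 0 — a permutation p of 0 is always an
artifact of too few permutations. The seed is a mandatory argument: a
permutation test without a recorded seed is not reproducible. Default
`n_perm = 999`; below 99 a warning flags the coarse resolution. Singleton
groups are allowed with a warning (their within-group term is zero),
matching common field practice with unbalanced designs. The test suite
checks the pseudo-F against vegan's implementation, Monte-Carlo p against
exhaustive enumeration on a 6-sample instance, and type-I calibration on
1000 exchangeable simulated nulls.

## Dimension reduction

PCA centers feature-wise but does **not** scale by default: abundance
variances are meaningful, and unit-scaling rare taxa inflates noise (a
scaling flag exists). Scores come from the SVD of the centered samples ×
features matrix, which is agnostic to whether samples or features are more
numerous. When fewer than `k` nontrivial axes exist (e.g. two samples),
the request is truncated to the available rank rather than erroring, so
the forced single axis carries explained variance 1.

PCoA applies Gower double-centering `B = −½ J D² J` and eigendecomposes.
Negative eigenvalues — which arise because Bray-Curtis is non-Euclidean —
are dropped without Cailliez/Lingoes correction, but their count and total
magnitude are reported in the embedding details so users can judge the
distortion; explained variance is relative to the positive spectrum only.
On Euclidean distance matrices PCoA reproduces PCA coordinates (checked to
1e-8).

Axis signs are arbitrary in both methods; each axis is oriented so its
largest-magnitude loading (or coordinate) is positive, making outputs
reproducible across numerically equivalent backends.

t-SNE and UMAP are contracts around optional backends (`Rtsne`, `uwot`):
fixed seed + fixed input ⇒ identical output, no explained-variance fields,
and a typed capability error when the backend is absent — the rest of the
toolkit does not depend on them.

## Differential abundance

Both paths share the interface: a two-level target covariate, optional
adjustment covariates, aggregation level, and a `min_count` filter on the
mean raw count across all samples (not per group, so feature selection
cannot depend on the contrast being tested). The reported `log2fc` is
oriented so positive values mean higher abundance in the target's first
factor level. Multi-level targets are rejected rather than silently
contrasted; recode explicitly.

### NB-Wald path

Per feature, a negative-binomial GLM with log link, the design
`[intercept, group, covariates]`, and `log(size factor)` offsets. Size
factors are the zero-tolerant median-of-ratios: per-feature geometric
means over strictly positive counts only, per-sample medians over features
positive in that sample, rescaled to geometric mean 1. The dispersion `α`
(variance `μ + αμ²`) is estimated per feature by profile maximum
likelihood on `[1e-8, 10]` from a method-of-moments start, with the
Cox-Reid adjustment `−½ log|XᵀWX|` — the GLM analogue of REML. Without it
the dispersion MLE is biased downward and the Wald test anti-conservative;
with it the simulated null type-I fraction sits near nominal (measured by
the test suite). The Wald statistic uses the Fisher information of the
final IRLS fit; p values are two-sided normal. Features whose IRLS
diverges (no convergence, |β| ≥ 15, or unstable information) are flagged,
their p set missing, and excluded from the BH denominator.

There is deliberately **no dispersion shrinkage toward a mean-dispersion
trend**: per-feature estimation keeps the method self-contained and its
behavior checkable by simulation recovery, at the cost of some power at
small n. Consequently this is a negative-binomial-Wald method *in the
style of* the established count-model packages, not numerically equivalent
to any of them, and its correctness is asserted against ground-truth
simulations rather than cross-package equality.

A known, documented limitation shows up in the recovery simulations: when
10% of the community shifts in one direction and compositions are not
renormalized, median-of-ratios size factors acquire a small group-
correlated bias, which inflates the empirical FDR above the BH nominal
level even though effect sizes and sensitivity are recovered well. The
acceptance report computes this FDR honestly rather than masking it; the
same inflation reproduces under an independent reference NB-GLM
implementation on identical matrices, identifying it as a property of
median-of-ratios normalization under unidirectional compositional shift,
not of this implementation.

### Moderated-t path

Ordinary least squares of logCPM on the same design, then empirical-Bayes
variance shrinkage: the prior degrees of freedom `d₀` and prior variance
`s₀²` are estimated by closed-form moment matching of `log s²` (digamma /
trigamma inversion, Newton iterations), the posterior variance is
`s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, and `t = β̂/(s̃√v)` is referred to a t
distribution with `d₀ + d` df. `d₀` can be fixed for diagnostic purposes:
0 reproduces the ordinary per-feature t test, `Inf` pools all features to
one variance; estimation failure (non-positive spread in `log s²`) falls
back to pooling with a warning. The hyperparameter estimates and moderated
t statistics agree with the reference empirical-Bayes implementation to
well under 1% in tests.

### Extended columns

Both paths report, per feature and group: mean relative abundance
("percentage"), prevalence, and the group-size-adjusted fold change
`(pct₁ + ε)/(pct₂ + ε)` with `ε = 1e-6`. The adjusted fold change had no
formal definition to inherit, so the ε-stabilized ratio of group mean
relative abundances was chosen: it is finite when a feature is absent from
one group, equals the naive ratio away from zero, and reads directly as
"how many times more abundant". The "percentage" column could plausibly
have meant percent of total reads; mean relative abundance was chosen and
is stated here so users are not misled.

## Biomarker discovery

The selection stage runs N-repeat, K-fold stratified cross-validation
(defaults N = 3, K = 3; each fold's class counts are within one sample of
proportional). Small K keeps folds class-balanced in small cohorts; larger
K is advisable for large ones. Per training fold, candidates are:

* `logistic`: features with nonzero coefficients in an L1-penalized
  logistic regression, with the penalty chosen by an inner 3-fold grid
  search over 8 log-spaced values spanning 1e-3…1e3 in inverse-penalty
  units (ties resolved toward the sparser model);
* `random_forest`: features with positive impurity importance, with the
  features-per-split grid {√p, p/3, p/5} chosen by out-of-bag error.

Candidacy needed a definition (only the importance *score* was specified):
sparsity-based candidacy was chosen because it makes the score — the
fraction of folds whose candidate set contains the feature — a meaningful
stability measure rather than a constant 1. `candidate_fraction` optionally
truncates each fold's candidates to the top fraction by importance; it is
exposed separately from the score cutoff `P` (default 0.20) because the
two knobs answer different questions (per-fold sparsity vs cross-fold
stability), and analyses in the field sometimes quote one while meaning
the other.

Evaluation deliberately **re-selects nothing**: a fresh CV (same K and N,
offset seed) uses the fixed selected panel, refits the model (including
its hyperparameter search) inside each training fold, and scores only
held-out samples — so no sample influences any fitting step of its own
fold. Per-fold ROC curves come from a threshold sweep over predicted
probabilities; the mean curve is the vertical average of fold TPRs on a
fixed 101-point FPR grid; the mean AUC is the mean of per-fold trapezoidal
AUCs. With fewer than 30 samples a warning urges extreme caution —
repeated CV cannot fully protect small cohorts from optimistic bias.

Under permuted-label nulls, a run can legitimately select nothing (every
fold's L1 path stays at the empty model); this raises an error advising a
lower `P` rather than fabricating an empty-model AUC.

## The synthetic-data generator

`simulateExperiment()` draws baseline taxon proportions from a symmetric
Dirichlet (default concentration 0.5 — a strongly uneven community with
many rare taxa, as is typical of 16S surveys), library sizes from a
log-normal with configurable mean (default 1e5 reads) and coefficient of
variation (default 0.3), and counts from a negative binomial with variance
`μ + αμ²` (default α = 0.2) — the same parameterization the NB-Wald path
estimates, which makes parameter recovery a well-posed check. A chosen
fraction of taxa carries a multiplicative group effect (group 1 higher by
`2^log2fc`); the remaining taxa are *not* renormalized, so the nominal
fold change stays exactly interpretable at the cost of a small
compositional footprint — the source of the FDR note above, and itself a
realistic property of real communities. Metadata carries the group factor
and a continuous nuisance covariate; the taxonomy randomly partitions taxa
into a configurable number of genera and phyla. All randomness flows from
one seed, and the generator restores the caller's RNG state.

`simulateTwoClusterProfiles()` perturbs the group-2 baseline by
`exp(divergence · z)`, `z ~ N(0,1)` per taxon, then renormalizes:
divergence 0 gives exchangeable groups (the PERMANOVA null), larger values
push between-group Bray-Curtis above within-group.

What the generator does **not** emulate: amplicon error profiles and
chimeras, zero inflation beyond what the NB produces, taxon-taxon
correlation structure, batch effects, or phylogenetic signal. Passing
tests therefore demonstrate correct statistical behavior under a clean NB
compositional model, not robustness to every artifact of real sequencing
data.

## Problem sizes and numerical choices

The test suite and the acceptance script use deliberately moderate problem
sizes — e.g. 1000 replicates × 199 permutations for PERMANOVA calibration,
10 simulation seeds × 200 taxa × 40 samples for NB recovery, 10 seeds of
50-taxon nulls for the biomarker — chosen so the whole battery runs in a
few minutes on one CPU while keeping Monte-Carlo error well inside the
asserted bounds.

Other numerical conventions: counts parsed from text accept floats within
1e-9 of an integer (some OTU pipelines emit `5.0`) and reject the rest;
PathoScope duplicate taxon rows are summed with a warning; the session
archive is a tar of TSV members plus a JSON manifest (counts round-trip
bit-exactly; numeric metadata is serialized at 17 significant digits and
restored to its recorded column type); BIOM output is v1 JSON in sparse
encoding with named metadata fields so taxonomy round-trips losslessly;
dispersion optimization runs on the log scale with tolerance 1e-4;
trigamma inversion iterates Newton to relative 1e-8.
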