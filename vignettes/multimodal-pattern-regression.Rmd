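---
title: "Multimodal pattern regression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal pattern regression: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(patreg)
```

`patreg` predicts continuous cognitive composite scores from multimodal
brain volumes — gray-matter (GM) and white-matter (WM) tissue-density maps
and PET-like cerebral blood-flow maps — and localizes the brain regions the
prediction relies on. This vignette explains the model and procedure, the
parameters that matter, what the synthetic cohorts do and do not emulate,
and the design decisions taken where the design was genuinely open.

## The problem and the modelling strategy

Mass-univariate mapping (one test per voxel) is well suited to asking
*where* an association is, but poorly suited to asking *how well* the brain
as a whole predicts a behavioural score, and it cannot pool complementary
information across modalities. The pipeline here takes the pattern-regression
view: reduce the voxel data to regional features, fit a flexible regressor
from regions to the score, validate it purely by out-of-sample prediction,
and then interrogate the fitted model for the regions it relies on.

The analysis runs separately for each cognitive domain and for each modality
set (single modalities and their combination), inside a leave-k-out
cross-validation loop. One split proceeds in three steps:

1. **Feature generation.** On the training subjects only, compute the
   voxelwise Pearson correlation `r(v)` between voxel value and the
   composite score; segment the mask with a marker-based 3-D watershed on
   the relief `-|r|` (peaks of `|r|` become basin cores), merge clusters
   below a minimum size into their most similar neighbour; each cluster
   becomes one feature: the mean voxel value over the cluster, per subject.
   Features from all modalities in the model are pooled and ranked by
   `|r(feature, score)|`; the top `3 (N_c - k_c)` (further capped by `fMax`
   at desk scale) enter selection.
2. **Model and selection.** A relevance vector regression (RVR) — kernel
   regression with independent Gaussian priors on basis weights whose
   precisions are optimized by evidence maximization — models the
   feature-score relationship. Recursive feature elimination removes one
   feature per iteration when doing so lowers the validation MSE, then a
   forward pass re-admits eliminated features under the same criterion, so
   low-ranked features that work jointly with kept ones are not lost.
3. **Aggregation.** The model is refit on the full training set with the
   selected features; predictions for the left-out subjects are recorded;
   the discriminative direction of the fitted regressor is painted onto the
   clusters as the split's spatial difference map. Predictions and maps are
   averaged over all splits, and the maps are min-max normalized jointly
   across modalities to [0, 1].

## The relevance vector regression core

With design matrix `Phi` (an RBF kernel on standardized features plus a
bias column), weight precisions `alpha` and noise variance `sigma^2`, the
posterior is Gaussian with
`Sigma = (diag(alpha) + Phi'Phi / sigma^2)^-1` and
`mu = Sigma Phi' y / sigma^2`. Evidence maximization iterates
`alpha_i <- (1 - alpha_i Sigma_ii) / mu_i^2` and
`sigma^2 <- ||y - Phi mu||^2 / (n - sum_i (1 - alpha_i Sigma_ii))`,
pruning basis functions whose precision exceeds `1e9`. Most precisions
diverge; the surviving training points are the relevance vectors. The
implementation (`rvrEM()`, in compiled code because RFE refits it hundreds
of times per split) is validated against the closed-form ridge solution it
must reproduce when the hyperparameters are frozen, and convergence is
declared when `max |delta log alpha| < 1e-3`.

Numerical choices: `alpha` starts at `1/n^2`, `sigma^2` at
`0.1 var(y)` (floored at `1e-6` for degenerate targets), a jitter of
`1e-10` stabilizes the posterior solve, and a symmetric positive-definite
solver is used rather than an explicit inverse. If every basis function is
pruned — the expected outcome on signal-free data — the model falls back to
predicting the training mean and is flagged, and downstream contributions
are zero.

The kernel width is the main hyperparameter the original method leaves
unstated. The default is the median heuristic,
`gamma = 1 / (d * median^2)` over pairwise distances of the standardized
training features, resolved once per split on the full candidate pool and
reused for every candidate subset — re-deriving it per subset would make the
RFE's MSE comparisons unstable. Results that depend on the kernel are
therefore method-level, not value-level, claims.

## Watershed clustering choices

The original description calls only for a watershed with "spatial
consistency constraints"; the concrete policy here is: markers are the
26-neighbourhood local maxima of `|r|` pre-smoothed at 4 mm FWHM, with
equal-valued plateau maxima collapsed to the lowest linear index (a uniform
relief therefore yields exactly one cluster); flooding is by priority queue
in decreasing relief order with FIFO tie-breaking, so the labelling is
deterministic; clusters below `minClusterVoxels = 10` are merged into the
26-adjacent cluster with the closest mean `|r|`, smallest cluster first.
Every mask voxel ends up labelled, and every cluster is 26-connected — both
properties are enforced in tests by an independent flood-fill oracle.

## Cross-validation, and a deliberate deviation on feature selection

`k_c = round(0.1 N_c)` subjects are left out per split. Enumerating all
leave-k-out subsets is infeasible (`C(80, 8)` is of order `1e10`), so R
balanced random splits are drawn; a deficit-greedy scheduler keeps
per-subject leave-out counts within one of each other.

One protocol detail required a decision with scientific consequences. In
the original description, the RFE criterion is the MSE on the k left-out
subjects — the same subjects whose averaged predictions are later reported.
Measured on a signal-free synthetic cohort (the regression test on the
`"leftout"` protocol in the suite), that circularity alone produces a
prediction-score correlation of about **0.8** (the permutation null band is
roughly ±0.22 at N = 80): feature selection can fit eight validation points
well even when no features carry information. The default here is
therefore a **nested** design: RFE is validated on an inner split (10% of
the training subjects), and the left-out subjects are touched only by the
final frozen model. On signal-free data the default pipeline's correlation
falls inside its own permutation null band, and shuffling the left-out
subjects' scores provably changes nothing about selection. The literal
protocol remains available as `cvConfig(rfeValidation = "leftout")` for
comparison with the original; its headline correlations should be read
with the inflation above in mind.

## Interrogating the model: discriminative direction and maps

For subject `s`, the gradient `g = df/dx` of the fitted regressor at the
standardized feature vector defines the discriminative direction
`sign(actual - predicted) g / ||g||` — the minimal-norm input change that
moves the prediction toward the true score. The per-feature contribution is
the mean absolute component of this direction over training subjects
(validated against a finite-difference oracle, and invariant to raw feature
scaling because gradients are taken in standardized space). Contributions
are painted onto their clusters, averaged over splits, and min-max
normalized jointly across modalities, which makes the per-voxel argmax
across modalities (the modality-maximum map) meaningful. The 0.2 overlay
threshold is purely a display convention; no computation thresholds.

Model comparison uses a paired permutation test: the observed statistic is
the difference in prediction-score correlation (or MSE) between two models,
and the null exchanges the two models' predictions per subject with
probability one half. The original reports only the comparison target and
the iteration count (10,000); both the statistic and an alternative null
(permuting the scores) are implemented, with the label-exchange scheme and
`delta_r` as defaults. Undefined correlations from zero-variance
predictions (intercept-only fits on null data) are mapped to zero, which
makes degenerate comparisons conservative rather than invalid.

## What the synthetic cohorts emulate

The generator plants a known brain-behaviour signal: a latent trait
`z ~ N(0, 1)` per subject; per modality, two spherical regions (radius 3
voxels) whose intensity is `base + beta_m z`; spatially smooth noise;
subject-level intracranial-volume scaling (uniform in 1.35-1.65 litres)
that `preprocessCohort()` must undo; and raw test scores
`a_t + b_t (z + eps)`, `eps ~ N(0, 0.5^2)`, in the four-domain battery
layout (3/3/2/2 tests), whose per-test affine scales the composite
construction absorbs.

Two generator choices deserve justification:

- **One latent trait shared by all domains.** The composites are treated as
  noisy measures of a single underlying ability — the simplest structure
  under which averaging tests into composites helps and prediction is
  meaningful. Real domains dissociate; this generator cannot test domain
  specificity.
- **Noise autocorrelation of half the filter width** (4 mm structural,
  6 mm PET, before the deliberate 8/12 mm preprocessing filters). Setting
  the intrinsic autocorrelation equal to the filter widths would double-count
  smoothing: after preprocessing the maps would be ~11 mm smooth, the
  correlation relief would support only a handful of watershed basins, and
  the regional-clustering premise of the method (hundreds of candidate
  regions, a `3 (N_c - k_c) = 216` pool cap) would be void. With the
  corrected value the relief yields on the order of 20-30 clusters per
  modality at desk scale — still far fewer than real data, a limitation
  discussed below.

The generator does **not** emulate anatomy, registration error, scanner
artifacts, domain-specific traits, or longitudinal structure. Passing
tests on these cohorts show that the machinery recovers planted linear
region-trait signal under realistic smoothness and head-size nuisance; they
do not certify performance on real RAVENS/PET data.

## Problem sizes used by the test suite

End-to-end checks run at the default study conditions — N = 80 subjects
(the long-term-memory sample size), 32^3 grid of 2 mm voxels, three
modalities — with R = 50 splits for the headline combined run (seed 0) and
R = 10 splits for the per-seed model-comparison runs over seeds 0-4, with
the ranked pool capped at `fMax = 40`. Permutation-test calibration uses
200 signal-free replicates of an 80-subject cohort on a 10^3 grid with
1,000 permutation iterations each (the original used 10,000 iterations for
a single comparison; 1,000 is ample to estimate a rejection rate at
alpha = 0.05 over 200 replicates). The null-pipeline check runs at R = 20.

## Known limitations

- **Spatial resolution of the maps is basin-limited.** A watershed basin
  around a correlation peak extends over the full descending slope of the
  relief, so painted contributions smear well beyond a planted region. At
  desk scale this is acute for PET: a 12 mm filter on a ~54 mm phantom
  supports only ~10 basins, and truth-aligned clusters cover about half the
  out-of-region mask. Decomposing a default run shows the out-of-region
  contribution mass is dominated by this smear (per-voxel means of ~0.1
  from truth-aligned clusters vs ~0.03-0.06 from noise clusters), which
  caps the inside/outside enrichment near 2 regardless of how well features
  are selected. On real-sized brains (2.5x larger per axis, far more relief
  texture) basins are proportionally much smaller.
- Backward/forward RFE is greedy; with small validation sets its accepted
  steps are noisy, and the selected sets vary across splits by design.
- The permutation label-exchange test is exact only under per-subject
  exchangeability of the two prediction vectors; with strongly correlated
  prediction structures it is approximate (its empirical size is checked by
  simulation).
- Grid equality is enforced instead of registration; inputs must already be
  in a common template space.
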