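---
title: "Probabilistic fusion of multi-rater tumor segmentations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic fusion of multi-rater tumor segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxfuse)
```

## The problem

Automatic tumor segmentation remains much harder than organ segmentation:
tumors are small relative to the scan, morphologically irregular, and
boundary evidence is weak. A standard remedy is to train several model
variants — for instance by changing the loss function between runs — and fuse
their per-voxel decisions. voxfuse implements the three fusion strategies
such an ensemble needs, the metrics to judge them, and the paired statistics
to compare them, together with a synthetic multi-rater generator so the whole
workflow can be exercised and validated without any imaging dataset.

Throughout, a *rater* is any source of a candidate binary mask (a trained
model, a human reader); all fusion methods treat raters symmetrically.

## Fusion models

**Majority voting** marks a voxel foreground iff strictly more than K/2 of
the K raters do. With even K, ties go to background. It uses no confidence
information at all.

**Soft voting** averages the raters' per-class probability maps (softmax
outputs) voxelwise with equal weights, then takes the per-voxel argmax
(ties toward the lower class index, so an exact 0.5/0.5 binary tie is
background). Confidence is used, but every rater counts equally.

**STAPLE** (Simultaneous Truth and Performance Level Estimation) treats the
unknown true segmentation as a latent variable and each rater j as a noisy
channel with sensitivity $p_j$ and specificity $q_j$. Given the decision
matrix $D_{ij}$ (rater j's call at voxel i), the EM iteration is

- E-step: $W_i = a_i / (a_i + b_i)$ with
  $a_i = \gamma \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}}$ and
  $b_i = (1-\gamma) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}$;
- M-step: $p_j = \sum_i W_i D_{ij} / \sum_i W_i$,
  $q_j = \sum_i (1-W_i)(1-D_{ij}) / \sum_i (1-W_i)$.

Reliable raters therefore earn larger log-odds weight in the consensus
$W$, which is finally thresholded to a binary mask. The consensus behaves
like a performance-weighted vote, which is why it can dominate both equal
weight strategies when rater reliability is heterogeneous.

### Parameters and defaults

| parameter | default | rationale |
|---|---|---|
| initial $p_j$, $q_j$ | 0.9999 | near-certain initialization; standard for fusing trained-model outputs |
| convergence tolerance | 1e-4 | on the max absolute change of any $p_j$, $q_j$ between iterations |
| max iterations | 100 | cap; `converged = FALSE` if hit |
| prior $\gamma$ | mean rater foreground fraction in the ROI | held fixed across iterations |
| ROI | `full_volume` | `union_dilated(margin)` optional, see below |
| threshold | user-chosen; `gridSearchThreshold()` | maximizes mean DSC, ties to the balanced operating point, then the smaller value |

Several of these are genuinely open design choices, resolved as follows:

- **Monitored convergence quantity.** Only a tolerance magnitude is standard
  in the literature for this workflow; we stop on the maximum absolute
  parameter change, the usual scale-free EM rule.
- **Prior.** $\gamma$ is fixed at the mean rater foreground fraction rather
  than re-estimated each iteration. Re-estimating the prior is known to
  collapse on tiny foregrounds (a tumor is a vanishing fraction of a CT
  volume); the fixed empirical prior is classic STAPLE practice.
- **ROI.** With sums over an entire volume, the background so dominates
  that every rater's specificity estimate is ~1 and uninformative — real
  volumetric studies observe exactly this. `union_dilated` restricts the EM
  sums to the union of rater masks dilated by a margin, making specificity a
  meaningful, recoverable parameter. It is exposed as configuration and
  never applied silently; the default remains the full volume.
- **Clamping.** $p_j, q_j$ are clamped to $[10^{-6}, 1-10^{-6}]$ before the
  log-domain E-step: the 0.9999 initialization and perfect-agreement inputs
  otherwise produce $\log 0$.
- **Per-class fusion.** STAPLE here is binary. `fuseMulticlass()` fuses each
  foreground class independently and composes labels with precedence to the
  higher class index (tumor over organ). Single-class use on the tumor mask
  is the default in the experiments.

## Loss functions

The forward values of the losses used to diversify ensembles are provided
for diagnostics: cross-entropy, Top-K, Dice, generalized Dice, and the
hybrid sums CE+Dice, TopK+Dice, CE+GDice. Two printed-form ambiguities were
resolved in favour of internal consistency:

- **Top-K sign and normalization.** The Top-K loss is implemented as the
  negative *mean* per-pixel cross-entropy over the selected hardest-pixel
  set, so that K = 100% recovers the cross-entropy loss exactly; selection
  is at pixel level and boundary ties include all tied pixels.
- **Generalized Dice weights.** "Inversely proportional to class frequency"
  is implemented with the squared-volume convention
  $w_c = 1/(\sum_i g_{ic} + \varepsilon)^2$ of the original generalized
  Dice formulation; exponent 1 is available via `exponent = 1`.
- Both region losses add $\varepsilon = 10^{-5}$ symmetrically to numerator
  and denominator, defining behaviour for empty classes.

## Evaluation metrics

DSC, Jaccard, precision and recall come from voxelwise confusion counts;
`JI = DSC / (2 - DSC)` is asserted as an invariant. Degenerate conventions
(stated because real pipelines do hit them): if truth and prediction are
both empty all four metrics are 1; otherwise any zero-denominator ratio
is 0.

**HD95** uses physical mm from the header spacing (anisotropic slices are
the norm in CT, with slice thickness up to several mm). Surface voxels are
foreground voxels with a face-adjacent background voxel, the volume border
counting as background. Both directed nearest-surface distance sets are
pooled and one 95th percentile is taken with linear interpolation between
order statistics (`quantile` type 7); both the pooling (vs
max-of-directed, available via `method = "max"`) and the percentile rule
are pinned because they are the two main sources of irreproducibility among
HD95 implementations. HD95 is undefined when either mask is empty; such
cases are excluded pairwise from HD95 aggregation and paired tests.

**Solidity** (foreground area / convex hull area) is computed in 2D on the
axial slice of maximal foreground area — "area" implies a 2D quantity and
the maximal-area slice is deterministic and representative. The hull is
rasterized with pixel centers on the hull boundary counting as inside. A 3D
variant (volume over convex-hull volume) is deliberately not offered: no
robust 3D convex hull is available in the supported dependency set, and the
2D definition matches how the quantity is used.

**Tertile stratification** ranks cases ascending by ground-truth tumor
volume (ties by case id) and splits them into contiguous groups as equal as
possible, remainder to the lower groups (63 cases split 21/21/21; 7 split
3/2/2).

## Comparison protocol

Per metric family (DSC, JI, HD95, precision, recall) the protocol tests
STAPLE vs soft voting, STAPLE vs each individual rater, and soft voting vs
each individual rater — $1 + K + K$ rows, 11 for the canonical five raters.
Majority voting is reported descriptively only. Benjamini–Hochberg
adjustment is applied within each metric family independently at
$\alpha = 0.05$.

The Wilcoxon signed-rank test discards zero differences (classic
convention; Pratt's variant is not used) and assigns mean ranks to ties.
For up to 25 non-zero pairs the two-sided p-value is **exact including
ties**: the null distribution of the rank sum over all $2^n$ sign
assignments is built by convolution (doubling the mean ranks makes every
mass point integral). This matters in practice — the canonical
all-differences-positive example has fully tied ranks, and only the
enumeration null gives its exact $2/2^6 = 0.03125$. Beyond 25 pairs the
normal approximation with tie correction and continuity correction is used;
it agrees with `stats::wilcox.test` on that path. The normality pre-test
sometimes used to justify the nonparametric choice is not implemented: the
nonparametric path is taken unconditionally.

## The synthetic generator

`makePhantom()` produces a tumor-like blob: an ellipsoid whose radius is
optionally modulated by a seeded angular field — smooth low-order harmonics
for lobulated shapes, narrow high-amplitude bumps for spiky ones — giving
direct control over the solidity regime (ellipsoids ≥ 0.95; the pinned
spiky setting, irregularity 1.5 with 10 spikes, measures < 0.7).

`corruptRater()` is the generative inverse of the STAPLE observation model:
inside the truth each voxel is kept with probability `sensitivity`; inside
the boundary band (truth dilated by `roiMargin` face-connected steps, minus
truth) each voxel switches on with probability `1 - specificity`; outside
the band, background. Specificity is *defined on the band* because
whole-volume specificity is ~1 regardless of rater quality. Optional
morphological boundary jitter (seeded dilation/erosion of random surface
patches) adds spatially correlated errors closer to real model disagreement
than i.i.d. flips alone.

`makeProbabilityMap()` emulates a softmax output consistent with a mask:
tumor probability is a logistic in the signed Euclidean distance (mm) to
the mask boundary plus seeded Gaussian noise, renormalized against the
background class; with no noise, thresholding at 0.5 reproduces the mask
for any sharpness.

**Study conditions.** The heterogeneous regime used by the validation suite
and the acceptance script is fixed once: 64³ voxels at 1 mm isotropic
spacing; lobulated phantoms (irregularity 0.15, 5 lobes) with semi-axes
drawn uniformly from 8–14 voxels; five raters with sensitivities 0.95,
0.90, 0.85, 0.70, 0.60 and band specificity 0.995 (margin 3, no boundary
jitter — the regime is defined by its Bernoulli rates, so the empirical
rates are exactly interpretable); probability maps with sharpness 1.5/mm
and noise SD 0.05; STAPLE threshold 0.5 (the EM weights are near-binary, so
results are insensitive to it). Validation problem sizes: 20 cases for
parameter recovery, 30 for the method hierarchy, 5 for the threshold
search. A single master seed fans out to per-case, per-rater child seeds by
fixed arithmetic, so adding cases never reshuffles existing ones.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: CT intensities and contrast behaviour, anatomy
(no kidney/liver context), spatially *correlated* model errors beyond the
optional jitter, systematic biases shared across raters (the corruption
model is conditionally independent given the truth, exactly STAPLE's own
assumption — the simulation is therefore favourable ground for STAPLE, by
construction), and the long-tailed case difficulty of clinical cohorts.
The in-silico hierarchy STAPLE ≥ soft ≥ majority mirrors the qualitative
finding reported for real kidney and liver tumor cohorts, but the absolute
metric levels here say nothing about clinical performance.

## Numerical and degenerate-input choices

- All EM arithmetic is in the log domain; the E-step posterior is formed as
  a logistic of `log b - log a` for stability.
- `checkSameGrid()` compares spacings within 1e-4 mm; nothing is ever
  resampled or reoriented — mismatched grids or NIfTI orientation codes are
  errors.
- An all-empty rater set is a degenerate-input error for STAPLE; a
  single-rater set is valid and returns the rater's own mask.
- Label volumes are written as integer NIfTI (`int16`), probability maps as
  4D floating NIfTI; non-integer data where labels are expected is an
  error, never rounded.

## Limitations

- Binary STAPLE only: no multi-label formulation, no spatially varying
  performance (Local MAP STAPLE), no rater pre-selection (SIMPLE).
- Losses are forward values only — there are no gradients and no training
  loop.
- The Wilcoxon exact path is $O(n \cdot \sum r)$ by convolution, fine for
  the intended per-cohort sizes but not for thousands of pairs (where the
  approximation is used anyway).
- HD95 via explicit surface-pair distances is exact but quadratic in
  surface size; it is intended for desk-scale volumes, not whole-body
  scans.
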