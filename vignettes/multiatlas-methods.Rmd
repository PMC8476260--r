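---
title: "Multi-atlas segmentation of small skull-base structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The foramen ovale is a canal a few millimetres wide in the skull base through
which a puncture needle must pass to reach the trigeminal ganglion. Its shape
and size vary between patients, it is tiny relative to the head CT volume that
contains it, and its boundary contrast against the surrounding bone is good
but its morphology is irregular — conditions under which anatomical prior
knowledge helps far more than intensity rules alone. Multi-atlas segmentation
brings that prior in directly: a library of previously segmented scans
("atlases": a gray volume plus an expert label map) is deformed onto the
target scan, each deformed expert label becomes one candidate segmentation,
and the candidates are fused into a consensus.

`atlasseg` implements the full pipeline as reusable components:

1. **selection** — rank all atlases by normalized cross-correlation (NCC)
   against the target and keep the top *k* (default 10; beyond roughly ten
   atlases accuracy saturates while cost grows linearly);
2. **registration** — for each selected atlas, a multiresolution affine
   alignment followed by a multiresolution cubic B-spline free-form
   deformation (FFD), both maximizing sampled normalized mutual information
   (NMI) by stochastic gradient ascent;
3. **propagation** — the atlas label map is carried through the recovered
   transform with nearest-neighbor interpolation;
4. **fusion** — majority vote (MV), STAPLE, or SIMPLE combine the propagated
   labels;
5. **evaluation** — Dice overlap, 95% Hausdorff distance (HD95) and average
   symmetric surface distance (ASD), all in physical millimetres.

Because no public cohort of skull-base CTs with foramen labels exists, the
package ships a phantom generator that emulates the study design end to end
(a 20-atlas library plus 10 held-out test cases) with known ground truth and
known deformations, so every stage is testable against oracles.

## Geometry conventions

A `volume` couples a 3-D array with voxel spacing (mm), origin (mm) and a
3×3 orthonormal direction matrix; the world position of 0-based voxel index
`i` is `origin + direction %*% (spacing * i)`. All distances, transforms and
metric values are computed in physical millimetres — surface distances on the
order of a voxel would be meaningless in index units whenever spacing is
anisotropic. NIfTI-1 and (uncompressed) MetaImage files round-trip these
fields through their headers.

Transforms map **fixed-image points to moving-image points** (the resampling
convention): warping a moving volume onto the fixed grid interpolates the
moving image at `T(x)` for every fixed voxel center `x`. In a
`transform_chain(affine, ffd)` the FFD displacement is evaluated at the
original fixed point, so the chain realizes `T(x) = A(x) + D(x)` and the
control grid needs to cover only the fixed domain (plus a one-control-point
margin that guarantees every interior point its full 4×4×4 support).

## Atlas selection

NCC is implemented in the standard product-of-deviations (Pearson) form

$$\mathrm{NCC} = \frac{\sum_i (T_i - \bar T)(F_i - \bar F)}
  {\sqrt{\sum_i (T_i-\bar T)^2}\,\sqrt{\sum_i (F_i-\bar F)^2}},$$

which is bounded in [−1, 1] and invariant to positive affine intensity
changes — the property that makes it appropriate when atlases come from
different scanners with non-standardized intensity scales. Selection scores
are computed after resampling each atlas directly onto the target grid under
the identity alignment (selection precedes registration), restricted to the
voxels inside both image domains so that background padding cannot dominate
the score. Ties are broken by atlas id so rankings are deterministic.

## Registration

**Metric.** NMI in Studholme's normalized form
$(H_1 + H_2)/H_{12}$ over a 32×32 joint histogram of min–max-scaled
intensities. Each optimizer iteration draws a fresh uniform random sample of
2000 fixed-grid voxels (seeded stream), maps them through the current
transform, and interpolates the moving image linearly; identical images under
the identity give 2, independent images approach 1. Cubic B-spline
interpolation (with the exact recursive prefilter) is reserved for producing
final resampled outputs, where quality matters more than speed.

**Transform model.** The affine stage optimizes all 12 parameters (3×3
matrix plus translation) about the fixed-image center. The FFD stage
optimizes the displacements of a uniform cubic B-spline control grid; the
displacement at a point is the tensor-product sum over its 4×4×4 nearest
control points with the uniform cubic basis
$B_0..B_3$ (a partition of unity). The finest grid spacing is 5 mm; coarser
levels double the spacing per level while the images descend a factor-2
Gaussian pyramid (anti-alias sigma = factor/2 voxels). At each level change
the refined grid is initialized by *evaluating* the coarse field at the new
control points rather than by exact dyadic subdivision; the small smoothing
this introduces is corrected immediately by the finer level's optimization,
and it keeps grid geometry free (the two grids need not be nested).

**Optimizer.** Stochastic gradient ascent with decaying step
$a/(A+t)^{\alpha}$ (defaults $a=1$ mm, $A=50$, $\alpha=0.602$). Because
binned intensities make the sampled metric piecewise constant in the
parameters, gradients are taken by *central* finite differences with a
perturbation of half a voxel (`fd_eps_voxels`) — large enough to move
samples across histogram bins. One-sided differences are deliberately not
used: on a noisy piecewise-constant objective they acquire a systematic bias
that accumulates into parameter drift. For the affine stage all 12 parameters
are differentiated each iteration (matrix entries scaled by the inverse
domain radius so a unit step means comparable physical motion). For the FFD,
every control-point component with support among the iteration's samples is
differentiated; a perturbation of one component only moves the samples inside
that control point's support, so the joint histogram is updated incrementally
and the full gradient costs little more than one metric evaluation. Support
weights below 0.01 are skipped — they cannot move a sample across a bin at
this perturbation scale. The update step is normalized by the gradient's
largest component, so coherent structure moves at full step length while
diffuse sampling noise decays with the schedule; the residual it leaves at
convergence is sub-voxel (the self-registration test bounds the whole
recovered field below one voxel, mean below 0.2 voxels).

**Presets.** The `"paper"` preset carries the published parameterization:
4 affine levels × 1000 iterations, 5 FFD levels × 3000 iterations, 5 mm
finest grid, 2000 metric samples, factor-2 pyramid. The default `"desk"`
preset keeps the same structure scaled to interactive sizes — 2 × 100 affine
and 3 × 200 FFD iterations — which registers a 64³ volume in a few seconds
and is what the test-suite simulations use throughout. Registrations are
bit-reproducible for a fixed `rng_seed` (the C++ cores draw from R's RNG
stream).

**What recovery means on the phantom.** Deformation-recovery checks compare
the recovered map against the known synthetic deformation over the *bone
shell*, where intensity structure makes the deformation observable. In the
phantom's uniform air and soft-tissue regions no intensity-driven method can
recover displacement (the metric is flat there), so errors averaged over the
whole volume would measure the phantom's emptiness, not the registration.

## Label fusion

**Majority vote.** Foreground iff strictly more than half the candidates
vote foreground; with an even number of raters a tie goes to background —
deterministic, and conservative for a structure that guides a puncture
needle.

**STAPLE.** The binary EM formulation: each atlas *j* is a rater with
unknown sensitivity $p_j$ and specificity $q_j$; the E-step computes the
per-voxel posterior foreground probability under the current parameters and
a fixed foreground prior, the M-step re-estimates
$p_j = \sum_i W_i d_{ij} / \sum_i W_i$ and
$q_j = \sum_i (1-W_i)(1-d_{ij}) / \sum_i (1-W_i)$, and the fused map is
$W \ge 0.5$. Initialization $p_j = q_j = 0.9999$; prior `"auto"` = the mean
foreground fraction of the stack over the region of interest, held fixed;
E-step products in log space; rates clamped to $[10^{-5}, 1-10^{-5}]$. With
a fixed prior the EM log-likelihood is non-decreasing, which the tests
assert.

*Region of interest.* EM statistics are restricted to the union of all
candidate foregrounds dilated by `roi_dilate` voxels. The default radius is
2 voxels — the scale of residual registration error. This choice matters
more than it looks: for a structure of a few hundred voxels, a generous ROI
(say 10 voxels, a ~40:1 background:foreground ratio) drives every estimated
specificity so close to 1 that a single confident positive vote outweighs
the prior, and the EM fixed point degenerates toward the *union* of the
candidate masks — systematic oversegmentation that can leave STAPLE scoring
below plain majority voting. At radius 2 the ROI keeps the prior near 0.15
and specificities near 0.97, where disagreeing votes carry comparable weight
in both directions. `roi_dilate = Inf` restores whole-volume behavior (used
by the generative-recovery tests, where foreground occupies ~30% of the
volume and no degeneracy arises).

**SIMPLE.** Round 0 takes the majority vote as the working estimate; each
round scores every retained atlas by Dice against the estimate, discards
those below `mean − alpha·sd` (default `alpha = 1`), never dropping below
`min_keep = 3` (when the rule would, only the worst-ranked go), re-fuses the
remainder by majority vote, and stops when nothing is discarded or after
`max_rounds = 5`. As `alpha → Inf` no atlas is ever discarded and the result
equals plain majority voting; re-fusion between rounds uses MV (not STAPLE),
keeping each round's estimate cheap and transparent. The audit trail records
every score and discard decision.

## Evaluation metrics

Dice is computed on voxel counts. Surfaces are the foreground voxels with at
least one of six face-adjacent neighbors background or outside the volume;
distances are Euclidean between surface-voxel *centers* in mm (no sub-voxel
mesh extraction — the definitions are stated on voxel sets). ASD averages
both directions' nearest-neighbor distances over the sum of both surface
sizes. HD95 pools both directions' nearest-neighbor distances and takes the
95th percentile with the linear-interpolation definition
(`stats::quantile type 7`); a per-direction max-of-percentiles variant is
available behind `pooled = FALSE`, since the robust variant's pooling
convention is not standardized in the literature. Degenerate cases are
explicit: two empty masks have Dice 1 (with a warning), an empty prediction
against a non-empty truth reports Dice 0 with `NA` distances and an
`empty_prediction` flag rather than fabricating a number.

## The phantom and what it does (not) show

`make_phantom()` builds a bright ellipsoidal bone shell (radii 13 × 11 × 9
mm, 3 mm thick) on an air/soft-tissue background in a 64³ volume at 0.5 mm
isotropic spacing, pierced by two oblique cylindrical channels of 1.5 mm
radius (left and right); the truth label marks each channel where it passes
through bone (about 170 voxels each). Intensities are CT-like (air −1000,
soft tissue 40, bone 1200) with Gaussian noise (sd 40) added *before* a
slight Gaussian smoothing (sigma 0.5 mm) — acquisition first, processing
last, the order a prepared atlas would have seen. `make_cohort()` emulates
inter-subject variation: each of the 20 atlas and 10 test members is the
base anatomy warped by its own random smooth B-spline deformation (10 mm
grid, control displacements uniform in ±3 mm — safely inside the
0.4 × spacing invertibility bound) with fresh noise; members whose warped
truth label is not a single 6-connected component are regenerated from a
derived seed, and a manifest records ids, seeds and deformation magnitudes.
Everything is a pure function of spec + seed.

What the phantom deliberately does **not** model: real skull geometry and
its asymmetries, CT physics (beam hardening, partial-volume spectra), scanner
protocol variation, and the morphological variability of real foramina.
Passing the test suite therefore demonstrates that the pipeline's components
are implemented correctly and interact as designed under controlled
variation — not that the pipeline attains any particular accuracy on
clinical CT. The benchmark on the default seeded cohort (20 atlases,
10 tests, both sides, all three fusers — the layout behind per-method
summary tables) is asserted only *qualitatively*: STAPLE and SIMPLE should
not fall below majority voting, the ordering reported in the motivating
study.

## Problem sizes and budgets

The test simulations use the desk preset on 64³ phantoms: a full affine +
FFD registration takes a few seconds, the 10-pair deformation-recovery suite
under a minute, and the complete 20/10-cohort benchmark (100 registrations,
shared across the three fusers and both sides) a few minutes on one CPU.
`scripts/acceptance.R` regenerates the cohort and benchmark from scratch at
whatever seed it is given.

## Known limitations

- The registration stack assumes moderate initial misalignment (the phantom
  cohort's few-mm scale); it has no exhaustive or feature-based
  initialization for grossly rotated or cropped inputs.
- The FFD is not guaranteed diffeomorphic; deformation magnitudes near or
  beyond the control-spacing invertibility bound can fold.
- Binary, single-structure fusion only; left and right canals are two
  independent binary runs sharing registrations.
- The stochastic optimizer's accuracy floor is sub-voxel but nonzero;
  applications needing exact parameter recovery at machine precision need a
  deterministic metric (dense sampling) and a second-order optimizer, which
  are out of scope here.
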