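---
title: "Methods: automated daily dose accumulation for MR-guided adaptive radiotherapy"
author: "doseAccum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated daily dose accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In MR-guided online adaptive radiotherapy (MRgART) a patient's plan is
re-optimized on a daily MRI before each treatment fraction. The dose each
fraction actually delivers therefore lives on a *different anatomy* from
the planning MRI. To judge whether the course as a whole is on track —
is the target still covered, are the organ-at-risk (OAR) limits still
respected — the daily fraction doses must be mapped back onto the
planning anatomy and summed. `doseAccum` implements that pipeline for a
five-fraction prostate SBRT protocol (36.25 Gy prescribed to 95% of
PTV_eval, 7.25 Gy per fraction) on a 0.35T MR-linac:

1. **Rigid alignment** of the daily MRI to the planning MRI, restricted to
   a target-focused box;
2. **Hybrid deformable registration** (contour + intensity) producing a
   displacement field;
3. **Dose warping** of the daily one-fraction dose into the planning frame;
4. **Progressive composite**: the warped delivered dose replaces the
   planned dose fraction by fraction;
5. **Constraint evaluation** against an institutional dose-volume template
   with a ±3% replanning trigger;
6. **Validation metrics**: Dice/Jaccard/Hausdorff between contours warped
   by different workflows, 3D gamma analysis between dose distributions,
   and two-sample t-tests on DVH metrics.

Everything runs on synthetic data: a pelvis phantom with *known*
ground-truth deformation fields makes each stage testable without
clinical images.

## Coordinate and data conventions

All lattices are axis-aligned with 0-based voxel indices and a
voxel-center world mapping `world_mm = origin + index * spacing`; axes are
x = right-left (RL), y = anterior-posterior (AP), z = superior-inferior
(SI), in millimetres. A `DisplacementField` uses the *pull-back*
convention: a planning-frame point `p` maps to the daily-frame point
`p + u(p)`, so daily data are resampled onto the planning grid by
evaluating them at the mapped points. This is the natural direction for
dose accumulation (one interpolation of the daily dose, no field
inversion), and the phantom's truth fields are generated directly in this
convention; the daily images themselves are synthesized through the
numerically inverted field.

## The synthetic phantom

The phantom emulates the study conditions rather than MR physics: 1.5 mm
isotropic voxels (the protocol's 0.15 cm TRUFI resolution) on a grid
cropped to 128³ (≈19 cm field of view) so everything runs at desk scale;
piecewise-constant organ intensities with additive Gaussian noise
(default SD 5 on a background of 100); no bias field. Organs are analytic
solids: a prostate/PTV ellipsoid (default radii 25 × 22 × 24 mm, ≈52 cc),
a rectum cylinder, a bladder ellipsoid, a 3 mm urethra cylinder with a
2 mm PRV expansion, two femoral-head spheres and a penile-bulb ellipsoid.
`PTV_eval` is defined, as in the clinical protocol, as the PTV minus any
overlap with OARs; the default geometry puts its volume inside the
reported clinical range (tens of cc). All organ geometry is exposed via
`defaultOrganParams()` and fits a 96³ grid, the size used for the
registration-bearing tests.

The **plan dose** is analytic: the prescription inside `PTV_eval` with a
small centre-peaked heterogeneity (up to 4%, emulating an SBRT hot spot),
and a Gaussian falloff `exp(-d²/2σ²)` with distance outside (penumbra
σ = 5 mm). It is rescaled so that `PTV_eval` D95% equals the prescription.
Because the DVH is binned (0.01 Gy), the rescale is a short fixed-point
iteration with the target biased a quarter-bin high — this keeps both
D95% within half a bin of 36.25 Gy *and* the V36.25Gy ≥ 95% coverage row
of the constraint template robustly satisfied. Without the heterogeneity
the target DVH would be a degenerate step function and both quantities
would sit exactly on a bin edge.

**Deformations** are sums of three smooth components with known analytic
structure: radial bladder filling (Gaussian envelope scaled by
`bladderFillScale − 1`), an anterior Gaussian rectal bump (peak
`rectalBumpMm`, width 15 mm), and a smooth random field built from white
noise on a coarse lattice at half the correlation length, Gaussian
smoothed, trilinearly upsampled and normalized to a peak magnitude. The
constraint `randomFieldAmpMm ≤ 0.45 × randomFieldCorrMm` keeps the map
`x + u(x)` diffeomorphic with margin; the Jacobian determinant is also
checked numerically (central differences) and a non-positive value is a
hard error. Daily contours are the truth-warped planning contours — the
ground truth must stay known, so no observer noise is added by default.
The per-fraction delivered dose is a re-plan on the daily anatomy: the
analytic dose model recomputed on the warped structures and scaled to one
fraction, exactly as an online-adaptive workflow re-optimizes daily.
Clinical cohorts do not pin down daily deformation magnitudes beyond
target volume changes, so amplitudes are parameters, not fixed
constants; the test suite uses ≤ 8 mm fields, the regime the clinical
agreement figures correspond to.

RNG: one integer seed, propagated to named substreams (noise, field) via
a deterministic hash, so each random component is individually
reproducible and a fixed seed yields a bit-identical phantom.

## Registration

**Focus region.** Registration optimizes only inside a box around
`PTV_eval`: its bounding box expanded by 30 mm RL/AP and 20 mm SI,
clipped to the image. The clinical platform evaluates its cost inside a
"ring structure" it does not define geometrically; here the focus box
*is* that support region, with the margins the protocol states, and a
`box` argument for users who want a different ring.

**Rigid stage.** Normalized cross-correlation (NCC) of the daily image
sampled at rigidly transformed planning points inside the box,
maximized by a deterministic multi-start: a coarse translation grid
(±8 mm, 4 mm steps), then Nelder-Mead refinement of all six parameters
(3 Euler angles about the box centroid, 3 translations). The commercial
system does not state its rigid metric; NCC is robust to the phantom's
noise and is the conventional choice for mono-modal MR-MR alignment.
The identity and the best coarse start are kept as candidates, so exact
self-alignment returns an exactly zero transform.

**Deformable stage.** A cubic B-spline free-form deformation (default
knot spacing 20 mm) composed with the rigid initialization:
`φ(x) = T_rigid(x + u_B(x))`. The cost is

    C = w_I · SSD(intensity) + w_C · Σ_s SSD(SDM_s) + λ · bending energy

where `SDM_s` is the truncated (±20 mm) signed Euclidean distance map of
structure `s` — a differentiable, grid-native stand-in for contour
surface distance. Both data terms are normalized to unit initial
magnitude, so the default weights `w_I = w_C = 1` are scale-free; λ
(default 0.05) penalizes mean squared second differences of the control
displacements. The moving image and contours are resampled through the
rigid transform once; the final dose warp uses the single composed field,
so dose is interpolated exactly once.

Optimization is multiresolution (2 levels, factor 2) over a control
lattice fixed in millimetres, with spectral (Barzilai–Borwein) gradient
descent safeguarded by Armijo backtracking. A monotone, deterministic
optimizer was chosen deliberately: the accepted-iterate cost trace is
part of the interface (it is asserted non-increasing in the tests), the
method needs no stochastic metric sampling, and on these smooth phantom
costs its convergence is indistinguishable from a quasi-Newton method at
a fraction of the bookkeeping. Analytic gradients come from the in-cell
derivative of the trilinear interpolant; convergence is declared at a
relative cost change below `1e-4` or the per-level iteration cap
(40/20 by default).

On the phantom's ≤ 8 mm truth fields this recovers the warped target at
DICE ≥ 0.95 and mean surface distance under one voxel — the synthetic
analogue of the clinical agreement regime; the clinical numbers
themselves require the patient MRIs and are out of scope.

## Accumulation and evaluation

The progressive composite after k of N fractions is
`Σ_{i≤k} delivered_i + (N−k)/N · planned_total`, voxelwise on the
planning grid. Dose warping is pure dose mapping (trilinear interpolation
at mapped points) with **no Jacobian energy correction**, matching
typical commercial DIR-based accumulation; the warp reports the covered
fraction of planning voxels, and the omission is an explicit, documented
toggle-point rather than a hidden assumption. With identity fields and
delivered = planned/N the composite reproduces the planned dose to
machine precision — the closed-loop sanity check the acceptance suite
runs.

DVH curves are cumulative ≥-dose histograms on binary masks (0.01 Gy
bins); Dx metrics interpolate linearly between bins (a per-voxel sorting
oracle is kept in the tests, not in the runtime path). The institutional
template ships as `defaultConstraintTemplate()`: target coverage rows
(V36.25Gy ≥ 95%, V34.4Gy ≥ 98%, V33.7Gy ≥ 99%, V38.78Gy ≤ 20 cc,
V43.5Gy ≤ 0.03 cc) and OAR rows for rectum, bladder, urethra PRV,
femoral heads and penile bulb. Percent deviations are signed *toward
violation* so one scalar per constraint feeds the ±3% replanning
trigger, which fires strictly above the tolerance ("more than ±3%").
The protocol does not say whether the ±3% applies to the dose or the
volume axis; it is applied to each constraint's native reported quantity
(the volume value for V-type rows), which is what a template-based
system can evaluate uniformly.

## Validation metrics

Dice and Jaccard are voxel-set overlaps; surfaces are face-connected
boundary voxels and distances voxel-center Euclidean via an exact
anisotropic distance transform. "HD max" is the classical Hausdorff
distance; "HD mean" is interpreted as the mean symmetric surface
distance: "mean HD" is not a standardized term, and the sub-millimetre
magnitudes clinical QA reports quote for it are only consistent with the
mean-surface-distance reading (a percentile-Hausdorff alternative would
be a one-line change on the same distance transforms). Gamma analysis is
global, defaulting to the conventional 3%/3 mm with a 10% low-dose
threshold (all three numbers are arguments), searched over a sorted
sub-voxel offset lattice with early termination. The two-sample t-test
defaults to Welch; a pooled-variance option is provided since published
workflow comparisons rarely state which variant they used and their
large p-values cannot adjudicate it.

## Numerical choices and degenerate inputs

* Trilinear interpolation hits lattice points bit-exactly (endpoint-exact
  lerps), so identity resampling and identity-field warps are
  bit-identical no-ops, and integer-voxel translations shift masks
  exactly.
* Masks warp as 0/1 fields thresholded at 0.5.
* Empty masks, empty targets, zero prescriptions, non-invertible
  deformation parameters, oblique NIfTI orientations, missing DICOM
  scaling attributes and nonuniform frame offsets are all explicit
  errors, not silent fallbacks.
* Self-registration returns an exactly/near-zero field because the
  normalized initial cost of identical inputs is zero and the optimizer
  takes no step.
* Zero-variance t-test samples return p = 1 (equal means) or 0 rather
  than erroring.

## Problem sizes

The packaged tests run the registration-bearing checks on 96³ grids at
the native 1.5 mm spacing (the full default is 128³, used where no
registration is involved), a seven-patient × five-fraction batch with a
reduced iteration budget, and the metric suites on small analytic
fixtures. These sizes were chosen so the whole suite runs in minutes on
one CPU while keeping every organ of the default geometry inside the
grid.

## Known limitations

* No MR physics (no bias field, no distortion), no intrafraction motion,
  no CT-equivalent densities: passing tests demonstrate the pipeline's
  correctness on smooth, known deformations, not registration accuracy on
  clinical image content.
* Dose warping without Jacobian weighting does not conserve integral dose
  under compressive fields (it is exactly conservative only for
  volume-preserving maps).
* The DICOM readers cover explicit-VR little-endian RT Dose / RT
  Structure Set objects with axis-aligned geometry; DICOM writing and RT
  Plan parsing are out of scope.
* Manual landmark-assisted DIR editing is represented only as externally
  supplied fields in `compareWorkflows()`; there is no interactive
  component.
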