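---
title: "Deformable dose mapping for combined EBRT and brachytherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable dose mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctdosemap)
```

## The accumulation problem

A combined cervical-cancer treatment delivers an external-beam course
(here 45 Gy in 25 fractions) and an intracavitary brachytherapy boost
(28 Gy in 4 fractions), each planned on its own CT. Between the two
acquisitions the patient's pose, bladder and rectal filling, and — because
of the inserted applicator — the whole pelvic soft-tissue configuration
change. Dose must be accumulated per anatomical tissue element, which
requires a voxelwise deformation field from the reference frame (the BRT
planning CT) to the floating frame (the EBRT planning CT). This package
estimates that field with a pyramidal, weighted-window Lucas–Kanade (LK)
optical-flow solver and provides the surrounding dose-accumulation and
evaluation machinery.

All grids use `(z, y, x)` axis order; displacement fields are stored in
voxel units of the reference grid and carry backward (pull) semantics:
output voxel `x` reads the input at `x + disp(x)`.

## Preprocessing: applicator in-painting

The applicator exists only in the reference CT, so its voxels would
otherwise drag the registration. `replace_applicator()` replaces every
masked voxel with an independent uniform draw from
`mean(ring) ± hu_halfwidth` where the *ring* is a morphological dilation of
the mask minus the mask (surrounding tissue), then applies a Gaussian blur
written back only inside a one-voxel dilation of the mask. Everything
outside that region is bit-identical to the input.

| parameter | default | meaning |
|---|---|---|
| `hu_halfwidth` | 200 HU | half-width of the uniform draw |
| `ring_width_voxels` | 2 | dilation width defining "surrounding tissue" |
| `blur_sigma_mm` | 1.5 mm | Gaussian blur of the replaced region |
| `seed` | 1 | RNG seed; the draw is reproducible and leaves the session RNG untouched |

The uniform (rather than Gaussian) draw follows directly from the
"random values in a range" formulation; the ring width and blur sigma are
unspecified upstream and are therefore exposed with the defaults above.
Blurring is restricted to the replaced region because blurring the whole CT
would erase the very detail the registration feeds on.

## Preregistration

`apply_rigid()` applies user-supplied translation/rotation parameters
(bone matching is done by eye in practice; there is no automatic rigid
stage). `affine_register()` then minimizes the mean-squared HU difference
between the reference and the affinely resampled floating image over the
12 affine parameters, multi-resolution (3 levels), using BFGS with
finite-difference gradients at each level. Two numerical points matter:

* **Overlap-domain metric.** Output voxels whose source position falls
  outside the floating volume are excluded from the metric rather than
  edge-clamped. With clamped samples included, the metric is biased and the
  optimizer converges up to several millimetres away from the true
  transform; with the overlap convention, known translations and scalings
  are recovered to ~1e-3 mm / 1e-3 on the smooth validation phantom.
* **Quasi-Newton rather than plain gradient descent.** Plain descent with
  backtracking stalls in the long, narrow valleys the 12-parameter problem
  produces (matrix terms trade against translations); BFGS converges
  reliably and faster. The objective itself — masked MSE, per the
  evaluation metric — is unchanged.

The affine result is handed to the deformable stage as an initial
deformation field (`affine_to_field()`), never as a resampled volume, so
the floating image is interpolated exactly once whenever the final
(affine + deformable) field is applied. Resampling after the affine stage
and registering the resampled image measurably degrades the deformable
stage: interpolation smooths the fine texture unevenly and the final field
is the composition of two interpolating maps.

## The Lucas–Kanade solver

At each voxel the flow solves the weighted normal equations
`(Σ w ∇I ∇Iᵀ) v = −Σ w ∇I I_t` over a `(2r+1)³` window. Implementation
choices, in the order they matter:

* **Window sums as separable convolutions.** The Gaussian-of-distance
  weight factorizes per axis, so all nine sums are exact separable
  convolutions (zero-padded: near the border the window simply contains
  fewer voxels). An explicit-loop oracle reproduces the compiled path to
  1e-8 on 9³ volumes.
* **Degenerate windows.** The 3×3 normal matrix is solved by truncated
  eigendecomposition: eigencomponents with eigenvalue below
  `min_eigen_factor × (window weight mass)` are zeroed. A homogeneous
  window yields a zero update; a window containing only a straight edge
  yields an update only along the measured direction. An all-or-nothing
  gate on the smallest eigenvalue would zero the update for *any*
  rank-deficient window and could not even recover the translation of a
  linear ramp, which the truncated solve recovers exactly.
* **Window weights.** `weight_sigma = 2r/3` by default, leaving the window
  edge with weight `exp(-9/8)` (about a third of the center). Much narrower
  weights shrink the effective window to ~2 voxels and with it the
  per-level motion capture range.
* **Iteration budget.** `iters_per_level = c(3, 10)` (finest level first;
  early stop when the mean update drops below 0.01 voxel). The coarse
  levels do the motion capture, are cheap, and average away intensity
  noise; at full resolution the unregularized estimator starts converting
  intensity noise into flow noise after a few iterations, so the finest
  level takes only short refinement. The per-iteration update is clipped at
  1.5 voxels per component.
* **Pyramid.** Each level Gaussian-smooths (sigma 1 voxel) and halves the
  in-plane resolution; the slice axis joins only while at least 8 slices
  remain, because 2.5 mm slices are coarse already. Fields propagate to
  finer levels by trilinear resampling with per-axis rescaling of the
  displacement components.
* **No field regularization.** The field is never smoothed or projected
  after solving, matching the method's design. `jacobian_report()` counts
  non-positive finite-difference Jacobian determinants as a diagnostic for
  folding instead of fixing them silently.

Flow is fully 3D; the window is isotropic in voxel units even though the
voxels are anisotropic in mm. The "neighborhood radius" parameterization is
authoritative: radius 3 means a 7×7×7 window, and two pyramid levels with
radius 3 is the optimized default.

## Dose accumulation

`eqd2()` applies the linear-quadratic conversion
`EQD2 = D(α/β + d)/(α/β + 2)` with the per-voxel fraction dose
`d = D/n_fractions` — the conversion is applied per distribution, so the
fraction dose must vary with the voxel, not sit at the prescription value.
Conversion happens **before** mapping and summation: EQD2 is nonlinear in
D, so conversion and trilinear warping do not commute, and converting at
the planning stage keeps each course's radiobiology tied to its own
fractionation. α/β defaults: 10 Gy for tumor-response reporting, 3 Gy for
organ-at-risk DVH parameters; both are plain arguments.

`map_dose()` warps with the same backward semantics as image warping, so
the mapped dose is spatially congruent with the registered image.
`landmark_dose()` averages the six face-adjacent neighbors of the voxel
center nearest the query point (the enclosing voxel is excluded — the
wording "six surrounding points" counts exactly six), which stabilizes
point doses in the steep BRT gradient. `dose_difference_report()` compares,
per landmark, `EBRT(floating point) + BRT(reference point)` against the
mapped-and-accumulated grid at the reference point; relative differences
are normalized by the global maximum of the accumulated grid.

## Evaluation metrics

* **Landmark distance** — Euclidean world-mm residual between the
  model-predicted floating position of each reference landmark
  (`x + disp(x)`, then any affine) and its annotated position. The
  convention (mapping reference points forward) matches the field's
  backward-warping direction; the opposite convention is available by
  swapping the roles of the columns in the landmark table.
* **RMSE** — root mean squared HU difference inside the patient contour
  (couch and air differences are excluded by construction).
* **2D gamma analysis** — per axial slice, 2 %/2 mm, local reference, HU
  standing in for dose. The discretized search scans a polar-sorted offset
  grid (radius `3 × dist_crit`, pitch `dist_crit/10`, bilinear evaluated
  values) with an early break once the pure distance term exceeds the
  current best; it matches an exhaustive brute-force search to 1e-6.
  Local denominators are floored at 1 HU to avoid division by zero near
  0 HU; `"global"` mode normalizes by the masked reference range, which
  keeps the score invariant under a common HU offset. The study score is
  the mean over evaluable slices.
* **DVH hot spots** — `dose_at_volume()` is the exact sorted-voxel
  estimator: D_v is the k-th largest masked voxel dose with
  `k = ceiling(v / voxel_volume)`; no histogram binning enters the value.
  `compare_accumulation()` sets the clinical standard (adding the two
  courses' D_v parameters) against the D_v of the deformably accumulated
  grid.

## The phantom: what it does and does not emulate

`make_case()` builds the study conditions: a 64×128×128, 2.5×1×1 mm pelvic
phantom (soft-tissue body, bone and organ ellipsoids at CT-typical HU), a
multi-scale random soft-tissue texture (a broad band, ±120 HU at
10–18 mm, and a fine band, ±80 HU at 2.5–6 mm — soft-tissue contrast at
roughly the fat-to-muscle span), additive Gaussian noise (sigma 10 HU),
three applicator rods at 1500 HU in the reference frame, and a ground-truth
deformation that is a sum of Gaussian bumps (widths 16–20 voxels,
amplitudes up to ~4 voxels, all-voxel Jacobian verified positive at build
time). Landmarks are sampled at high-gradient voxels away from the
applicator and volume border and are paired *exactly* through the field.
The EBRT dose is a wide, nearly uniform plateau (a whole-pelvis
prescription) plus a smooth boost deliberately offset from the applicator,
so the EBRT and BRT hot spots do not coincide anatomically; the BRT dose is
a capped inverse-square falloff around source points on the rods (steep
near-applicator gradients; the cap of 60 Gy physical keeps the EQD2 range
clinically shaped). Everything is deterministic under the seed.

`make_smooth_phantom()` is a separate validation fixture for
motion-capture and affine-recovery checks: a global intensity ramp (the
gradient never vanishes), broad blobs that survive downsampling, and fine
blobs that decorrelate under multi-voxel motion. It exists because the
anatomy phantom's sharp organ edges limit every pyramid level's capture
range to about two voxels: with sharp edges everywhere, a 6-voxel
translation defeats a two-level pyramid no matter the window, whereas the
smooth fixture isolates the mechanism the pyramid is supposed to
demonstrate — coarse capture on smooth content, fine refinement on detail.

What passing on these phantoms does *not* show: real CTs contain
scanner-specific noise and artifacts (streaks, beam hardening near the
applicator), sliding organ interfaces that violate the smooth-deformation
assumption, intensity changes that are not motion (gas pockets appearing
and disappearing), and genuinely extreme inter-fraction reconfigurations —
the regime in which this class of unregularized method is known to fail.
Ground-truth fields here are smooth and invertible by construction;
clinical accuracy claims require clinical landmarks.

## Problem sizes and runtime

The validation suite registers the full 64×128×128 phantom (about 1M
voxels) through the complete chain — in-painting, affine, two-level LK,
gamma over all slices — in roughly two minutes on one CPU; unit tests use
16×48×48 cases and 9³–16³ oracle volumes. These sizes were chosen so the
whole suite runs comfortably on a laptop while still exercising the
full-resolution code paths.

## Known limitations

* No oblique direction cosines: axial, axis-aligned acquisitions only.
* The affine stage can absorb part of a purely deformable discrepancy
  (any MSE-optimal affine will); the deformable stage then has to undo it.
  The composite-field architecture makes this cheap but not free.
* Unregularized LK accumulates flow noise in homogeneous tissue if
  over-iterated at full resolution; the iteration budget mitigates but
  does not remove this, and `jacobian_report()` should be consulted for
  folding on difficult cases.
* DICOM support is deliberately minimal (explicit VR little endian,
  axis-aligned geometry, no compression) — enough to ingest planning
  exports and to round-trip the package's own writer, not a general
  toolkit.
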