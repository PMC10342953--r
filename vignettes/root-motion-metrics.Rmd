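---
title: "Quantifying 3D aortic root motion from surface displacement fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D aortic root motion from surface displacement fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootmotion)
```

## The problem

The aortic root moves through the cardiac cycle: the contracting left
ventricle pulls it downward (axially), shifts it within its own plane,
tilts and twists it, and the pressure pulse dilates the lumen.
Deformable registration of ECG-gated dynamic CT angiography yields a
vertex-wise displacement field on a triangulated surface of the
diastolic aortic wall — the diastole-to-systole motion of every surface
point.  `rootmotion` turns that raw field into the interpretable root
motion metrics used in clinical research: directional displacements,
area ratio and distensibility, axial tilt, aortic rotation, and the
LV/Ao angle, plus the nonparametric cohort statistics needed to compare
patient groups.

The package deliberately does *not* perform segmentation or
registration; it consumes their outputs (a mesh, a displacement CSV,
a landmarks JSON) and owns everything downstream.

## The measurement plane

All root metrics are evaluated in an *analysis plane* at the sinuses of
Valsalva, at the level of the coronary ostia — a location with distinct
anatomic features that registers reliably.  `plane_at_ostia()` projects
both ostia onto the aortic centerline, takes the centerline point at the
mean of the two arc-length parameters as the origin, and uses the
centerline unit tangent there as the plane normal.  Conventions that the
clinical definition leaves open are fixed deterministically:

* the normal points from the root toward the arch (the direction of
  increasing centerline sample order), so "downward" LV pull has a
  negative axial sign (the sign is retained in `axial_signed`; the
  reported axial displacement is a magnitude);
* the in-plane basis `u` is the normalized cross product of the normal
  with the global axis least parallel to it, and `v = n × u` — an
  arbitrary but reproducible choice, so repeated runs agree
  bit-for-bit;
* the centerline is resampled by arc length (0.5 mm spacing by default)
  before the central-difference tangent, which regularizes tangents on
  coarsely sampled centerlines.

`slice_mesh()` intersects each triangle with the plane and stitches the
segments into closed loops using shared mesh-edge identity, so the two
triangles adjacent to an edge contribute bit-identical crossing points
and stitching needs no distance threshold.  When the plane also cuts
other parts of the vessel (e.g. the arch returning alongside), the loop
whose centroid is nearest the plane origin is kept — the origin is by
construction inside the root lumen.  Vertices lying exactly in the
plane are treated as displaced by +1e-12 mm along the normal, making
every crossing transversal; the resulting near-duplicate points are
merged (1e-7 mm).

## Displacement metrics

The total root displacement is the displacement field averaged over the
lumen contour at the analysis plane.  Two estimators are provided:

* the default is the exact arc-length-weighted (line-integral) mean of
  the piecewise-linear contour, with the field interpolated linearly
  along each crossed mesh edge.  This estimator has no dependence on
  where the loop starts, so it is invariant under rigid transforms of
  the whole subject to floating-point precision — a property we verify
  to 1e-6 and that a fixed-count resampling estimator cannot achieve
  (its start phase shifts under rotation, leaving an O(h²) artifact);
* `samples = 256` reproduces the conventional equal-arc-length
  resampling average; it converges to the integral mean as the sample
  count grows and agrees with it to ~1e-4 on the meshes used here.

Averaging over the contour rather than over raw mesh vertices removes
mesh-density bias: a locally refined patch would otherwise dominate a
vertex average.

The mean displacement vector `d` is decomposed against the diastolic
plane normal `n`:

* total = |d|, axial = |d·n|, in-plane = |d − (d·n)n|;
* relative axial = axial/total, relative in-plane = in-plane/total,
  so `rel_axial² + rel_inplane² = 1` whenever the total is nonzero.

A subject with exactly zero mean displacement has undefined relative
components; they are reported as missing (`NA`), never as 0.

## Areas, distensibility, tilt and rotation

The systolic configuration of the contour is obtained by warping the
diastolic contour points with their interpolated displacements.  Warped
points are only approximately planar, so a plane is first fitted to
them (`fit_plane()`, Newell-method normal with the orientation anchored
to the diastolic normal) and the systolic area and centroid are
computed in that fitted plane.  The planarity tolerance for warped
contours is 0.5 mm by default (vs 1e-6 mm for exact slices) and is
configurable for pathological fields.

* **Area ratio** = systolic / diastolic contour area (shoelace formula
  in the plane basis).
* **Distensibility** = (area ratio − 1) / pulse pressure, reported in
  10⁻³ mmHg⁻¹ — the conventional inverse-stiffness index.
* **Axial tilt** = acute angle between the diastolic and systolic plane
  normals (the systolic normal is flipped to the diastolic hemisphere
  first).  Observed tilts are a few degrees, so acute vs raw is
  immaterial in practice; the acute convention makes the metric robust
  to a fitted-normal sign flip.
* **Aortic rotation** = angle between the centroid-to-reference vectors
  of the two phases, both projected into the diastolic plane.  The
  reference is the left coronary ostium; its systolic position is the
  diastolic landmark moved by the displacement interpolated at the
  nearest mesh vertices (inverse-distance over the 3 nearest; exact
  when the landmark is a mesh vertex).  Each vector is anchored at its
  own phase's centroid, so a pure translation of the root produces
  exactly zero rotation.  The unsigned angle is reported (the signed
  value, positive counterclockwise about the diastolic normal, is kept
  in `rotation_signed_deg`).

All angles are computed as `atan2(|v1 × v2|, v1 · v2)` — never a bare
`acos` — so collinear configurations cannot produce NaN from round-off.

### The LV/Ao angle convention

The LV/Ao angle φ is defined pictorially in the clinical literature as
the angle between the lines perpendicular to the aortic and mitral
annuli.  A line-based angle is ambiguous up to the orientation of each
normal, so the package fixes the convention explicitly: the
aortic-annulus normal is oriented toward a point up the ascending aorta
and the mitral-annulus normal toward the LV apex, and φ is the angle
between these oriented normals.  A heart whose LV outflow is coaxial
with the root then gives φ = 180° (anti-aligned oriented normals), and
annulus axes 47° apart give φ = 133°, inside the 120–140° range
reported clinically.  The convention is calibrated once to that range
and not revisited.

## The phantom: analytic ground truth

Real cohort data cannot ship with a package, and no closed-form truth
exists for a patient's motion.  The phantom module therefore provides
the validation surface: a tube along +z with radius profile

r(z, θ) = R + b(z)·(1 + cos 3θ)/2,

where b(z) is a Gaussian bump (amplitude 4 mm, width 7.5 mm by
default) centered at the sinus level — a three-lobed sinus-of-Valsalva
cross-section on a 15 mm root.  Defaults (65 rings × 128 vertices over
60 mm) resolve the contour to well below the metric tolerances.  The
coronary ostia are surface vertices of the sinus ring, 120° apart; the
centerline is the z-axis; annulus rings for the LV/Ao angle are
included with a built-in 130° angle.

The prescribed deformation composes, about the analysis-plane origin:
in-plane dilation (factor s), twist about the normal, tilt about an
in-plane axis, then rigid translation.  At the small magnitudes used
the composition order affects the plane-level truth below tolerance;
the order is fixed and documented for reproducibility.  Motion is
constant at and below the plane and decays as `exp(−h/decay_length)`
above it (default 20 mm) — root motion is transmitted from the
ventricle below, and a constant-at-plane profile keeps the ground truth
analytic:

* axial displacement = prescribed axial translation;
* in-plane displacement = |prescribed in-plane translation| (dilation
  and twist average to zero over the symmetric contour);
* tilt = prescribed tilt; rotation = prescribed twist;
* area ratio = s² (an in-plane linear scale squares the area).

Two constructions make the truth *exact* rather than approximate: the
axial grid always contains a ring at the sinus level, and the slicing
rule treats on-plane vertices as epsilon-above, so the analysis contour
coincides with that ring and samples the field where the decay weight
is exactly 1.

Randomized validation draws deformations uniformly from ranges spanning
the motions observed clinically: axial 0–8 mm, in-plane 0–6 mm, twist
0–5°, tilt 0–6°, dilation 1.00–1.15.  Recovery tolerances used in the
tests are 2% (relative to the total displacement) for displacements,
0.3° for angles and 1% for the area ratio; the observed worst-case
errors are orders of magnitude smaller for displacements/areas and
~0.13° for the rotation (the residual comes from projecting a tilted
configuration back onto the diastolic plane, a second-order effect of
order tilt²/4).

With vertex jitter of 0.05 mm — a plausible segmentation noise level —
displacement recovery degrades gracefully (tested < 5%).

What the phantom does **not** emulate: real registration error fields
(spatially correlated, anisotropic), branch vessels and the arch,
out-of-plane curvature of the root axis, or imaging artifacts.  Passing
the phantom suite shows the *metric extraction* is correct, not that
any upstream registration is.

## Cohort statistics

Group sizes in root-motion cohorts are small (~10 per group), so the
package follows standard nonparametric practice.  `kruskal_wallis()`
is implemented directly from the rank formulas (mid-ranks for ties, the
`1 − Σ(t³−t)/(N³−N)` tie correction, chi-square p on k−1 df) so that it
is checkable against hand computation; base R's `kruskal.test` serves
as an independent cross-check in the tests, to 1e-12.
`kruskal_wallis_exact()` enumerates the exact permutation law for small
samples: at N ≤ 8 the chi-square p deviates from the exact p by up to
~0.11 in the instances we enumerate, which is why small-cohort p-values
near the threshold deserve skepticism — the package documents this
approximation error rather than hiding it.

Pairwise group comparisons are two-group Kruskal–Wallis tests without
multiplicity adjustment (matching the per-pair p-value convention of
cohort tables; Holm adjustment is available via `adjust = "holm"`).
Group tables report mean ± sample (n−1) SD and ranges.  `linear_fit()`
implements ordinary least squares with the slope t-test and the
pointwise 95% confidence band from the closed forms; its type-I error
at n = 200 is verified by simulation to sit at the nominal 0.05 within
±0.02.

## Registration QC

The registration's visual alignment check is summarized by the Dice
coefficient between the fixed diastolic mask and the warped systolic
mask (`dice_overlap()`, `overlap_report()` for a per-slice profile).
Dice is the standard overlap score for registration QC; no published
pass/fail threshold exists for this application, so the package only
warns (default below 0.95) and never fails a pipeline on it.  Two empty
masks score 1 with a warning — vacuous agreement must not break empty
ROIs.  Masks read/write NIfTI (via RNifti) and NRRD.

## Numerical choices and degenerate inputs

* Degenerate triangles are rejected above 1e-12 mm²; plane bases are
  orthonormal to 1e-9; contour planarity defaults to 1e-6 mm for exact
  slices.
* Slices that cannot be stitched into a closed loop (open surfaces
  ending across the plane) are an error naming the offending mesh
  edge, not a silent partial contour.
* An ostium projecting beyond the centerline span is an error naming
  the landmark.
* Collinear annulus points make the fitted plane an error, not a
  garbage normal.
* Zero total displacement flags the relative components as undefined.

## Problem sizes

The validation suite runs phantoms at 128 circumferential × 65 axial
vertices (8,320 vertices) for the reference and sweep checks, 96 × 49
for the 20-transform rigid-invariance check, and 24–96 circumferential
for convergence; the statistical simulations use 500–1,000 replicates.
These sizes put every check far below its tolerance while keeping the
full suite around half a minute on a single core.

## Limitations

* Metrics are evaluated at a single analysis plane; gradients of motion
  along the root (plane-position sensitivity) are not quantified.
* The mean-displacement estimator weights the lumen *contour*, not the
  enclosed wall area; for strongly asymmetric fields these differ.
* Wall strain/stress tensors and multi-phase (more than two time
  points) cyclic metrics are out of scope.
* The statistics module implements the tests the field conventionally
  applies; it does not attempt age-matching or multivariable
  adjustment.
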