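---
title: "Models and methods: fiducial calibration, trajectory planning and targeting evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fiducial calibration, trajectory planning and targeting evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctnav)
```

## The problem

In robot-assisted percutaneous needle placement under cone-beam CT
(CBCT) guidance, a lightweight robot arm holds a needle guide at a
planned pose while the interventionist inserts the needle manually.
Three software problems sit at the core of such a system, and this
package implements all three:

1. **Robot-to-image calibration.** A calibration tool attached to the
   robot is imaged inside the CBCT volume. The tool is a
   radiotranslucent plastic slab containing four hollow (air-density)
   spheres whose pairwise distances are all different. Detecting the
   spheres and identifying them through their distance signature
   yields the rigid transform between the imaging world frame and the
   robot/tool frame without any manual labelling.
2. **Trajectory planning.** The clinician selects an entry point A and
   a target point B in the volume; the plan is the line segment AB,
   decomposed into craniocaudal and RAO/LAO angulation and checked
   against the system's reachable envelope (17.5° cranial, 32.5°
   caudal, ±20° RAO/LAO).
3. **Targeting evaluation.** After insertion, the actual tip C is
   compared with the plan through three error components: the angular
   deviation D between AB and AC, the absolute deviation |BC|, and the
   longitudinal deviation |CC′|, where C′ is the planned-depth point
   on the actual trajectory.

No public dataset exists for this setting, so the package ships a
synthetic phantom generator that renders CBCT-like volumes of the
calibration tool with exact ground truth, and a Monte-Carlo workflow
simulator that stands in for the physical experiment. Everything
downstream is tested against those generators.

## Coordinate conventions

All lengths are in mm and angles in degrees. The world frame is LPS
(Left–Posterior–Superior, the DICOM patient convention). Voxel indices
are 0-based and map to world coordinates as
`world = origin + direction %*% (index * spacing)`; the default volume
is isotropic at 0.48 mm/voxel, which is the control-scan resolution
the error analysis is premised on (at that resolution the planned and
actual entry points are indistinguishable, so the evaluation treats
them as identical).

Craniocaudal angulation is the arcsine of the superior component of
the needle direction, positive toward the head. RAO/LAO is the angle
of the axial-plane projection away from the anterior–posterior axis,
positive toward the patient's right (RAO). A purely craniocaudal
direction has an undefined RAO/LAO angle and returns 0 by convention.
The sign conventions are this package's choice: only the limit
magnitudes are physically fixed, and the RAO/LAO limit is read as
±20° (whether it is ± or total is not documented; ± is assumed).

## The calibration tool model

The real tool's in-slab sphere coordinates and diameters are not
public. The shipped default geometry is therefore invented, and
documented as such: four points realising the pairwise distance set
{11, 16.4, 21.8, 27.2, 32.6, 38} mm with sphere radius 4 mm inside the
200 × 75 × 30 mm tool envelope. Three properties drove the choice:

* **Signature gaps.** Adjacent distances differ by 5.4 mm, above the
  5 mm `min_signature_gap` floor, so the shipped coordinates keep the
  margin even after finite-precision storage. The gap is what makes
  correspondence matching robust: with a 0.96 mm distance tolerance
  (two voxel edges) no two assignments can be confused unless
  centroids are off by several voxels.
* **Conditioning.** Among all edge-assignments of that distance set to
  a tetrahedron, the one maximising the smallest principal extent of
  the point cloud (≈6.6 mm) was chosen. A nearly coplanar cloud makes
  the out-of-plane rotation ill-determined; the chosen geometry keeps
  all three rotational degrees of freedom observable.
* **Field of view.** The cloud radius is ≈21 mm, so the tool fits a
  192³ volume (92 mm cube) near the centre, and a 288³ volume (138 mm
  cube) for poses translated up to 40 mm.

A seeded random generator (`make_tool_model(seed = )`) exists for
property tests; the default is fixed so every downstream result is
deterministic.

## Phantom rendering

`render_phantom_volume()` paints background soft tissue (40), a
plastic slab (100) as the axis-aligned box enclosing the posed
fiducials plus margin, hollow spheres at air density (−1000) and
optional lesions (70) into the grid, then adds i.i.d. Gaussian noise.
Sphere edges are antialiased: each voxel blends between inside and
outside level linearly over one voxel edge of signed distance to the
surface. This mimics the partial-volume effect of a real
reconstruction and is what gives centroiding its subvoxel accuracy —
with hard-edged spheres the centroid of the thresholded voxel set
would be biased by up to half a voxel.

What the generator deliberately does **not** emulate: projection-domain
physics (scatter, beam hardening, cone-beam artefacts), deformation or
breathing motion, and streak artefacts from metal. The scan protocol
(200° rotation, 0.5°/frame, 397 projections, 6 s) is carried as inert
metadata only. Passing tests on this generator therefore demonstrate
the geometric correctness of the pipeline, not robustness to real
reconstruction artefacts.

## Detection and matching

Detection is deliberately simple: threshold at −450 (midway between
air and plastic), label 26-connected components, filter by voxel count
(≥10) and equivalent-sphere radius (1.5–8 mm), and compute
intensity-weighted subvoxel centroids. At ≈30 HU-equivalent units of
noise the air/plastic contrast is ~37 standard deviations, so recall
is limited by geometry, not noise; the filters exist to reject noise
specks and lesions in less contrasted configurations. A refinement
pass (`refine_centroid`) recomputes the centroid on a
background-subtracted spherical window of 6 mm radius; the support is
kept below half the closest fiducial spacing so a neighbouring sphere
cannot bias the estimate, and the window is aligned to the voxel grid
so refinement is exactly idempotent once converged.

Matching enumerates all 4-subsets of up to 20 candidates and all 24
assignments per subset, keeps those whose six pairwise distances each
agree with the model within 0.96 mm, and returns the assignment with
the smallest post-fit fiducial registration error (FRE). Exhaustive
enumeration (≤116k assignments) is fast at this scale and makes
correctness auditable against ground-truth labels. If a runner-up
assignment also passes the distance tolerance and its FRE is within
1.5× of the best, the match is declared ambiguous and refused —
mirroring the tool's design intent that unique distances resolve
correspondence, and catching degenerate (e.g. square) geometries.

The rigid fit itself is the closed-form SVD solution of the
orthogonal Procrustes problem with the determinant constrained to +1;
collinear sources are refused. Tests cross-check it against an
independent numerical optimiser over axis-angle parameters.

## The outcome simulator

The physical experiment's deviations cannot be recomputed from data
that does not exist, so `simulate_needle_outcome()` models the two
error sources the robot does not control:

* an angular error of the realised needle direction about the planned
  axis, with the two transverse components independent
  N(0, `angular_sd_deg`), default 0.68°;
* a manual depth error N(0, `depth_sd_mm`), default 1.55 mm, so the
  realised tip is `C = A + (|AB| + ε_d)·R(û)`.

The defaults are set to the study-scale dispersion reported for a
robot-assisted phantom experiment (angular and longitudinal STDs), so
the simulator's marginals are comparable to — though not a
reproduction of — that study. Under this model the angular deviation
D is Rayleigh-distributed with mean `angular_sd·√(π/2)` and the
longitudinal deviation is half-normal with mean `depth_sd·√(2/π)`;
the tests verify both against Monte-Carlo oracles. Procedural time is
Gaussian truncated at zero (337 ± 50 s in-plane, 380 ± 26 s
out-of-plane by default). Iteration count is fixed at zero,
reflecting that the guided procedure needed no needle repositioning.

`simulate_study()` reproduces the study design: eight lesions, each
targeted once in-plane (craniocaudal = 0) and once out-of-plane
(craniocaudal tilt of at least 3° so the groups are cleanly separated
from the 1° classification tolerance), angles drawn 1° inside the
reachable envelope, depths uniform in 80–120 mm — a plausible
abdominal insertion range; the lesion coordinates of the physical
phantom are unpublished, so the default eight lesion centres are fixed
invented positions and the lesion radius (5 mm) is a parameter.

## Evaluation definitions

For entry A, target B and tip C, the package computes the angle
between B−A and C−A; the Euclidean |C−B|; and |C−C′| with
`C′ = A + |AB|·(C−A)/|CA|`. C′ is defined on the **actual**
trajectory at planned depth, so the longitudinal term isolates the
manual-depth error; the alternative reading (projecting C onto the
planned line AB) measures a lateral quantity and is rejected — with a
trajectory fixed by the guide, depth is the only error the operator
still controls. Group summaries use the sample (n−1) standard
deviation. The one-way ANOVA is computed from sums of squares directly
(between/within mean squares; p from the F survival function); with
zero within-group variance the F statistic is reported as `Inf`
(p = 0) for unequal means and 0 (p = 1) for identical groups. Tests
verify the two-group F = t² identity against an independent pooled-t
implementation and the null-uniformity of p-values.

## Numerical choices

* Angulation limits are inclusive, compared with a 1e-9° guard so a
  direction constructed exactly at a limit decomposes as reachable.
* `match_fiducials` reports `ambiguity_ratio = FRE_best/FRE_second`
  (∞ when unique); the refusal threshold 0.67 corresponds to the
  runner-up being within 1.5× of the best.
* The float32 wire encoding of a rotation matrix violates exact
  orthonormality; the decoder re-projects to the nearest rotation via
  SVD, keeping the rigid-transform invariant (1e-9) intact while
  staying within float32 round-trip tolerance (1e-6).
* The CRC-64 uses the ECMA-182 polynomial in an MSB-first, zero-init,
  no-xor configuration; 64-bit words are carried as two unsigned
  32-bit halves in doubles because R lacks native 64-bit integers.
* Problem sizes in the shipped tests: detection/recall at 192³ voxels,
  calibration round-trips at 288³ (the 40 mm translation range plus
  the 21 mm tool radius requires a ≈138 mm field of view at 0.48 mm
  spacing; 192³ would clip the spheres and the renderer refuses
  clipped geometry), Monte-Carlo marginals at 10⁴–10⁵ draws.

## Known limitations

* The renderer's slab is an axis-aligned world box rather than a posed
  copy of the physical tool housing; only the sphere geometry is
  pose-accurate. This is irrelevant for calibration (driven by sphere
  centroids) but means slab-edge appearance is not realistic.
* Detection assumes the spheres are resolvable as separate blobs; at
  noise levels where air and plastic distributions overlap
  (noise_sd ≳ 200) thresholding would fail. No shell model of the
  hollow sphere is attempted — at 0.48 mm voxels the solid-blob
  approximation is sufficient.
* The simulator draws angular and depth errors independently; any
  operator-induced correlation between them (e.g. harder angulations
  inserted more cautiously) is not modelled, and the procedural-time
  model is purely marginal.
* The protocol implements only the TRANSFORM and POINT message types
  (the two the workflow needs) with a reduced POINT record of bare
  coordinates; no network transport is included, messages are byte
  vectors and file dumps.
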