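---
title: "Sparse point-to-bone registration with axis-constrained perturbation search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse point-to-bone registration with axis-constrained perturbation search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpps)
```

## The registration problem

Computer-aided orthopedic surgery registers a preoperative bone surface
model (POM) to the intraoperative patient. When the intraoperative data are
a handful of bone-surface points digitized by a tracked A-mode ultrasound
probe, two features dominate the problem: the point set is *sparse*
(6–25 points is realistic), and each point carries an ultrasound point
localization error (UPLE) of up to a couple of millimetres. On a long bone
the sparse-point objective is nearly flat along the distal–proximal axis —
a femur is locally cylinder-like — so the standard iterative closest point
(ICP) algorithm reliably finds a minimum, but often the wrong one: poses
slid along, or spun about, the long axis score almost as well as the truth.

`icpps` implements a four-step pipeline that attacks exactly this failure
mode, and a Monte-Carlo framework for mapping accuracy as a function of
point count and noise level.

## The model and the four steps

A registration is a proper rigid motion (R, T): rotation matrix with
det = +1 plus a translation, all lengths in mm, angles in degrees at the
API surface.

**Step 1 — pre-registration.** Six of the sample points are measured, two
each, in three labeled anatomical areas (greater trochanter, 30 mm diameter;
medial and lateral epicondyles, 20 mm each). Each point is paired with the
centroid of its area's labeled vertices and the mean-squared-residual
objective

$$f(R, T) = \frac{1}{n}\sum_{i=1}^{n} \lVert x_i - (R u_i + T)\rVert^2,
\qquad n = 6,$$

is minimized in closed form by the SVD (Kabsch) construction. The closed
form attains the global optimum of this objective; an SVD solution with a
reflection is corrected by flipping the smallest singular vector. The 1/n
factor does not move the minimizer but is kept so the reported objective is
a mean squared residual.

**Step 2 — ICP.** Each iteration finds, for every sample point, the closest
point on the POM, then rigidly fits the correspondence pairs (the same
closed form). The iteration cap is 30. An update is applied only when it
does not increase the point-to-surface distance (below), which makes the
recorded trace provably non-increasing; an inner tolerance of 10⁻⁶ mm²
improvement stops the loop early, which does not change results at the
10⁻⁵ mm² precision the feedback loop works at.

**Step 3 — perturbation search.** The point-to-surface distance

$$\mathrm{PSD} = \frac{1}{n}\sum_{i=1}^{n}\lVert s_i - u_i\rVert^2$$

(mean of squared closest-point distances, mm²) is evaluated for the
registered points under every candidate of a curved grid around the bone:
rotations about the distal–proximal axis from −5° to 5° in 1° steps crossed
with translations along the axis from −3 mm to 3 mm in 0.5 mm steps —
11 × 13 = 143 candidates, endpoints included. The best candidate is
accepted only if it *strictly* lowers the PSD.

**Step 4 — feedback.** After an accepted perturbation, ICP is re-run from
the perturbed pose, and perturbation + ICP repeat until the PSD improvement
drops below 10⁻⁵ mm², with at most 5 repetitions. The stopping rule is
expressed as an improvement (PSD falls monotonically here, so the literal
signed difference of successive PSDs would always be negative and therefore
always "converged"). Because perturbations are only accepted when strictly
better and ICP never worsens the PSD, the final PSD can never exceed the
PSD after the first ICP pass.

**Accuracy metric.** Per-point errors flatter a registration of a long
bone, so accuracy is scored *bone-to-bone*: the residual motion (estimated
registration composed with the true displacement) is applied to **all**
model vertices and the root-mean-square per-vertex displacement is
reported, in mm. It is zero exactly when the registration inverts the
displacement.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| ICP iteration cap | 30 | – | standard budget for this pipeline; convergence is typically reached in ~10 |
| ICP inner tolerance | 1e-6 | mm² | stops stalled inner loops below the feedback loop's resolution |
| grid rotations | −5…5 step 1 | deg | axial spin range the coarse pre-registration can leave behind |
| grid translations | −3…3 step 0.5 | mm | axial slide range; 0.5 mm resolves sub-millimetre minima |
| feedback tolerance | 1e-5 | mm² | PSD convergence criterion of the feedback loop |
| feedback cap | 5 | rounds | bounds runtime; in practice 1–2 rounds suffice |
| displacement bounds | 10°, 20 mm | – | "arbitrary new location" of the simulated bone; inside pre-registration's capture range yet far from trivial |
| closest-point mode | vertex | – | see below |

Ties among equal-PSD grid candidates are broken by the smaller perturbation
magnitude `sqrt(rot_deg² + trans_mm²)` (identity first), then by enumeration
order, so searches are deterministic. The rotation axis of the grid is the
line through the model's vertex centroid along its distal–proximal axis —
the centroid is the natural reproducible rotation center, and the
distal–proximal axis is obtained as the first principal component of the
vertex cloud with the sign convention that its z-component (or, if zero, its
x-component) is non-negative.

### Vertex vs triangle closest points

The closest-point search has two modes. `"vertex"` (default) returns the
nearest mesh vertex through a k-d tree — the right choice on CT-density
meshes (~1 mm vertex spacing), where the vertex-to-surface gap is far below
the errors of interest and the search is fast. `"triangle"` returns the
exact nearest point on any triangle (point-to-triangle projection with
bounding-box pruning seeded by the nearest vertex); it removes the upward
bias of vertex distances on coarse meshes and is the mode to use with
decimated or synthetic low-density surfaces. Both modes agree that distance
zero means "on the surface" in their own sense, and triangle distance never
exceeds vertex distance.

## The synthetic femur

CT-derived femur meshes are patient data, so all simulation runs on a
procedural stand-in (`generate_synthetic_femur()`), a closed surface of
revolution with angular modulation: a gently waisted 400 mm shaft of 15 mm
radius along z with a 6 mm anterior bow, an offset femoral head
(radius 24 mm) and greater-trochanter bump proximally, and two condylar
bulges distally. Region labels mimic an intraoperative accessibility map:
the posterior shaft sector and the articular surfaces are inaccessible, the
rest accessible, with the three pre-registration disks (and four optional
mid-shaft disks) carved from the accessible area. Disk membership uses
Euclidean (chord) distance from an anchor vertex; at 20–30 mm diameters on
these curvatures the difference from geodesic disks is negligible.

Two generator choices matter for fidelity:

* **Vertex density.** The default 1 vertex/mm² reproduces the vertex
  spacing of a CT-segmented femur surface (~37 700 vertices at this size),
  which is the regime the vertex-mode pipeline is designed for.
* **Irregular vertex placement.** Vertices are sampled at seeded, jittered
  lattice positions rather than on regular rings. A regular lattice puts
  whole rings of vertices in phase, so the discretization error of
  vertex-mode distances oscillates coherently with axial misalignment and
  the PSD landscape grows artificial ripples that can mask genuinely better
  perturbation candidates. Segmented CT meshes have no such coherence.
  Jittering keeps the lattice topology — the mesh stays watertight and
  consistently wound — while making the vertex distribution irregular.

The generator is deterministic given its seed and parameters, and it
*retains* the axial near-symmetry that makes the problem hard: plain ICP
started 3 mm along the axis from the truth, on mid-shaft points only, stays
at least 1 mm wrong in essentially every trial — this is the local-minimum
regime the perturbation search exists for, and the test suite asserts it.

What the synthetic femur does **not** emulate: real cortical-surface
texture, segmentation artifacts, anatomically exact condyle/neck geometry,
inter-patient shape variation, and any property of real ultrasound physics
(the noise model below is isotropic by construction). Passing tests
therefore demonstrate the algorithmic claims — local-minimum escape,
monotone PSD, accuracy trends in point count and noise — on femur-like
geometry, not clinical accuracy on patient data.

## The Monte-Carlo framework

A trial (`run_trial()`) samples ground-truth points from the model by the
two-step protocol (two random vertices from each pre-registration disk,
the rest uniform over the accessible vertices), displaces them by a random
rigid motion (rotation axis and translation direction uniform on the
sphere; angle and norm uniform up to the bounds), adds noise, registers,
and scores the bone-to-bone RMSE of the transforms after steps 2, 3 and 4
by re-scoring the recorded trace. Ground-truth points are mesh vertices,
matching the vertex-mode scoring and the dense-mesh assumption.

The UPLE is modeled as a vector in a random direction uniform on the unit
sphere with magnitude uniform on a preset interval (0, [0, 1] or [1, 2] mm
in the standard design); the drawn magnitude is stored per point. The full
factorial design — point counts 6–25 × three noise intervals × 100
repeats — enumerates 6000 trials per method. Trial seeds are derived from
the master seed by counter-based hashing of the factor *values*, so adding
design levels never changes existing trials, and both methods share seeds
so they face identical inputs. Every number in the output table is
reproducible from the master seed.

The incremental evaluation (`incremental_uple_evaluation()`) emulates a
repeated-measurement protocol: each of 25 areas is measured 10 times with
noise, only the closest (minimum stored error) or farthest (maximum) point
per area is kept, the kept points are sorted by descending error, and both
methods register cumulatively from 6 to 25 points. The six
pre-registration points always participate (the coarse step needs them);
the remaining points join strictly in descending error order. Here the
stored simulated noise magnitude plays the role that an externally measured
per-point error would play in a physical experiment.

## Numerical choices and degenerate inputs

* Rigid fits reject fewer than 3 correspondences and collinear/coincident
  configurations (second singular value of the cross-covariance ~0);
  degenerate meshes (all vertices coincident) are rejected by the axis
  extraction.
* The PSD of an empty point set is an error, not NaN.
* STL files are accepted in both binary and ASCII dialects; the facet soup
  is indexed by exact coordinate match, and malformed files produce a parse
  error naming the byte where the file ends or breaks. Coordinates survive
  a write/read roundtrip to float32 precision (the STL storage type).
  Region labels live in a sidecar JSON next to the STL.
* ICP records its PSD per iteration; an update that would raise the PSD is
  discarded (the iteration then counts as converged), which is what makes
  the monotonicity guarantees hold exactly rather than approximately.
* Perturbation rotations are applied about the axis line through the model
  centroid; applying the single best candidate once per feedback round (not
  a multi-start) matches the sequential design of the pipeline.

## Problem sizes used in the tests

The test suite runs entirely on procedurally generated geometry: the
default-density femur (~37 700 vertices) shared across files, a coarse
femur (density 0.12) for structural checks, and small cylinders/patches
(≤ ~5 000 vertices) where a brute-force oracle must stay cheap. Monte-Carlo
assertions use 100 seeded trials for the monotonicity and near-perfect
registration rates, 20 repeats × 20 point counts for the accuracy-vs-count
trend, and 30 trials for the mid-shaft local-minimum regime; these sizes
give stable rates for the properties asserted while keeping the suite
comfortably interactive. The full 6000-trial design is enumerated exactly
but executed only at reduced scale.

## Known limitations

* Vertex-mode PSD is biased upward on coarse meshes; use triangle mode
  there (the package provides it; the default follows the dense-mesh
  pipeline).
* The perturbation grid is one-dimensional in each factor and axis-locked:
  misalignments outside the axial spin/slide subspace (e.g. a tilt of the
  axis itself) are only fixed insofar as the subsequent ICP pass fixes
  them. For bones without a dominant axis the grid axis from principal
  component analysis is not meaningful.
* The noise model is isotropic with uniform magnitude; real ultrasound
  error decomposes into calibration, speed-of-sound and tracking components
  with direction structure the package does not model.
* Non-rigid deformation, scale estimation, and probabilistic (e.g.
  Gaussian-mixture) registration are out of scope.
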