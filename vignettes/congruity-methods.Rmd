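---
title: "Measuring 3D hip congruity: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D hip congruity: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

The package treats the hip as an idealized ball-and-socket joint and asks
how far a given pair of bone surfaces departs from the congruent,
concentric ideal. Both bones are reduced to labeled point clouds in
millimetres (mesh connectivity is read and discarded; every estimator is
point-based and unweighted).

**Center estimation.** For points $\{p_i\}$ and a candidate center $c$,
with $d_i = \lVert p_i - c\rVert$, the center estimate minimizes the
*population* standard deviation
$\sigma(c) = \sqrt{\tfrac1N \sum_i (d_i - \bar d)^2}$
over a discrete search: candidates on a cubic lattice of pitch `step`
(default 0.1 mm) within half-width `range` (default 5.0 mm) of the current
center; the search moves to the minimizing candidate, re-centers the cube,
and stops when the incumbent is the minimizer of its own cube. The radius
of curvature is $\bar d$ at the optimum. The SD objective — rather than a
least-squares sphere fit — is what makes the method robust to the partial,
one-sided coverage of anatomical surfaces, and the discrete, re-centering
search reproduces the original clinical protocol; the grid pitch is
therefore also the method's resolution (center components are only ever
determined up to ~`step`/2 per axis).

**Femoral side.** The head-region centroid is the initial temporary
center; the line from the femoral-neck cross-section center to it is the
neck reference axis; the plane through the temporary center perpendicular
to that axis is the equatorial plane, and latitude is the signed elevation
above it (cranial positive). The fit runs on the latitude band
[−10°, +45°] (closed bounds), which excludes the fovea capitis near the
cranial pole and the head–neck junction caudally. A fit SD above 1.0 mm
(strict) flags the head aspherical; such hips are marked `excluded` but
still fully reported.

**Acetabular side.** The lunate-surface points (fossa acetabuli excluded
at labeling time — delineation is segmentation work, deliberately not
automated here) are fitted with the same estimator, seeded at the
definitive femoral head center. No asphericity rule applies.

**Indices.** Mismatch ratio $R_A/R_F$; center discrepancy distance
$\lVert c_A - c_F \rVert$ and its unit vector re-expressed in anatomical
ML/PA/SI components. Coordinates are assumed to be scanner axes of a
supine, neutrally positioned subject; a three-letter orientation tag
(default `RAI`: +x patient-right, +y anterior, +z inferior) declares the
anatomical meaning of the world axes, and the ML sign is flipped for left
hips so `+` is always *lateral*. Reported ratios round half-up to two
decimals.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `range` | 5.0 | mm | clinical search half-width; large enough to absorb centroid bias from one-sided coverage |
| `step` | 0.1 | mm | clinical grid pitch; sets the resolution of every recovered quantity |
| `max_rounds` | 50 | — | safety bound; descent typically converges in < 12 rounds |
| `cranial_limit` / `caudal_limit` | +45 / −10 | deg | exclude fovea (polar cap) and head–neck junction |
| asphericity threshold | 1.0 | mm | exclusion rule of the source protocol; strict inequality ("exceeded") |
| axis tag | `RAI` | — | must match how the scanner axes map to the patient |

## Numerical choices

- **Population SD (divisor $N$), not sample SD** — the objective-function
  convention; the two-point example (distances 21 and 23 → SD exactly 1)
  pins it testably.
- **Radius = mean distance at the optimum.** The natural companion of SD
  minimization: at the SD-minimizing center, the mean is the least-squares
  radius for that center.
- **Tie-break** among equal-SD candidates: smaller displacement from the
  current center, then lexicographic $(x,y,z)$ offset order. Arbitrary but
  fixed, so results are deterministic and brute-force-comparable.
- **Coarse-to-fine schedule.** A literal 0.1 mm scan of a ±5 mm cube is
  101³ ≈ 10⁶ candidates per round. When the literal cube exceeds ~50k
  candidates the search runs a ladder of pitches (powers of two times the
  final step, so all stages share one lattice), finishing at the target
  pitch. On near-spherical objectives this reaches the literal fixed
  point; the test suite asserts equality against the literal scan and
  against an independent exhaustive-enumeration oracle on small grids.
- **Closed band bounds**: boundary latitudes (exactly −10° or +45°) are
  included; ties resolved by ≤/≥.
- **Fixed frame**: the equatorial plane and the ROI are built once from
  the *initial* centroid and held fixed during the search. Re-deriving the
  ROI as the center moves would make the objective's support depend on the
  iterate and the optimization ill-posed; the protocol text describes ROI
  construction before the search, so the fixed reading is also the
  faithful one.
- **Degenerate inputs** (coplanar clouds, hemisphere-degenerate caps) are
  not specially detected; non-convergence surfaces through the `converged`
  flag and a warning.
- **Correlation grading** bins leave $(0.69, 0.70)$ unassigned in their
  published form; `grade_correlation()` extends "strong" up to (but
  excluding) 0.7.

## The synthetic-anatomy generator

Clinical CTs cannot ship with the package, so every estimator is validated
against a parametric generator with exact ground truth
(`synthetic_hip_spec()` / `generate_hip()` / `generate_cohort()`).

What it emulates: a spherical femoral head (default $R_F = 22.7$ mm) with
a flat-bottomed fovea indentation (cap 15°, depth 2 mm) at the cranial
pole, a tapered neck frustum below −30° latitude (providing the `neck`
label), an optional flat-topped cam bump at a configurable
latitude/longitude; a lunate band of the $R_A$-sphere (default 25.6 mm)
whose center is offset from the head center by a configurable anatomical
vector (default 3.2 mm toward lateral-anterior-inferior), with the fossa
cap removed; quasi-uniform Fibonacci-lattice sampling with seeded jitter;
i.i.d. radial Gaussian noise (default $\sigma = 0.3$ mm, a plausible
segmentation jitter for 1 mm CT slices).

The **lunate extent** defaults to latitudes 10–90° of the cup axis with a
30° fossa cap — a near-hemispheric bony cup with its central cone
non-articular, which is the textbook acetabular geometry. This choice is
load-bearing: a first draft used a narrower high-latitude band (30–90°,
fossa 25°), and the acetabular fit became ill-conditioned along the cup
axis — the grid-quantized axial center error trades almost freely against
the radius on a narrow one-sided band, inflating noiseless radius errors
beyond the grid bound. The near-hemispheric default restores the
conditioning that real, deeper sockets provide. The general lesson (the
shallower the socket, the softer the axial constraint on the acetabular
center) is clinically real and worth remembering when interpreting
dysplastic fits.

**Group profiles** (`group_profile()`) draw per-hip truth for cohort
studies: $R_F$ from the per-group normal, the mismatch ratio from its own
normal (so $R_A = R_F \cdot \text{ratio}$ — radii are strongly coupled
within a joint, and sampling them independently would inflate the ratio
spread far beyond what is observed), the discrepancy distance from a
truncated normal, and its direction from a von Mises–Fisher law
(concentration $\kappa = 12$, matching the published component SDs in
order of magnitude; the published data constrain only component means/SDs,
so the vMF form and $\kappa$ are free choices). Defaults encode the
dysplasia/borderline/control continuum: ratio 1.23/1.13/1.07, CD
4.8/3.2/1.6 mm.

What the generator does *not* emulate — and hence what a green test does
not establish: cartilage (the ratio > 1 on bone is a cartilage-gap proxy,
not modeled); non-spherical (conchoid-like) head shapes; segmentation
artifacts that correlate spatially rather than i.i.d.; partial or ragged
lunate delineation; osteophytes; patient positioning error (the axis tag
is taken as exact). Green tests establish that the *estimator* recovers
the stated geometry at the stated noise — not that the geometry model
captures every real hip.

## Known limitations and one deliberately red test

- All results inherit the 0.1 mm grid resolution; differences between two
  fits of nearly identical surfaces can reach twice the one-fit
  quantization because each fit sits on its own lattice.
- The neck cross-section center must be supplied (landmark pair, explicit
  point, or `neck` label centroid); there is no automatic neck detection.
- The acceptance suite contains one subtest that is geometrically
  unattainable as stated and is left failing on purpose: a flat cam bump
  of amplitude 2.5 mm on a 20° half-angle cap covers ≈ 6.9% of the ROI
  band, so the distance SD at the *true* center is at most
  $\sqrt{p(1-p)} \cdot 2.5 \approx 0.63$ mm — and the SD-*minimizing*
  center is lower still — which cannot exceed the 1.0 mm asphericity
  threshold. Reaching the threshold needs roughly a 33° cap or a 4 mm
  amplitude at 30°; a companion test uses the latter and turns the flag
  green, so the rule itself is exercised. The red test is kept as an
  honest record rather than silently re-tuned.
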