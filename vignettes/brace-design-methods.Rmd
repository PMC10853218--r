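---
title: "Automated nighttime brace design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated nighttime brace design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nightbrace` implements an automated design loop for nighttime braces in
adolescent idiopathic scoliosis (AIS): from a trunk model of the patient it
derives an over-corrected initial brace, then optimizes the brace surface
topography so that the *simulated* in-brace correction and the *simulated*
two-year growth outcome are as good as possible while skin contact pressure
stays below a pain threshold.  This vignette describes the models, every
tunable that matters, and the boundaries of what the synthetic test bed can
and cannot show.

## The design loop

1. **Patient** — a synthetic scoliotic trunk anatomy (or any anatomy in the
   same format): vertebral frames T1–L5, pedicles, pelvis, skin mesh.
2. **Standing calibration** — find the weightless geometry and stabilizing
   muscle forces so that gravity reproduces the presenting spine.
3. **Initial brace** — mirror the T2–L4 pedicles about the sagittal plane
   with a stepwise weight `W` (0 → 1 by 0.1), stop when element distortion
   exceeds a threshold, extract and trim the deformed skin.
4. **Parameterization** — a cylindrical 6 × 6 patch grid over the brace;
   the design vector is the 36 per-patch radial offsets in [−25, +25] mm.
5. **Evaluation** — supine in-brace simulation (gravity posterior, mattress,
   penalty contact, 60 N straps) → in-brace metrics and plate stresses;
   compliance-weighted stress combination (`C = 0.33`) → Hueter–Volkmann
   growth rates → two-year post-growth geometry → objective score.
6. **Optimization** — radial-basis-function surrogate search over the
   offsets with a pressure feasibility constraint (< 450 kPa).

## The synthetic patient generator

The generator *defines the study conditions*.  Its defaults emulate a
moderate nighttime-bracing cohort: MT Cobb 28 ± 8° [17, 44], TL/L Cobb
31 ± 9° [17, 48], kyphosis 27 ± 11° [13, 44], lordosis 42 ± 19° [16, 77],
apical rotations 5 ± 4° and 8 ± 7°.  Scalars are drawn from truncated
normals on those ranges; apex levels uniformly in T5–T10 (MT) and T11–L3
(TL/L); the MT curve is convex right and the TL/L curve convex left, the
most common presentation.

Geometry is built from three per-level angle profiles:

* **Coronal** — the lateral tilt is a shape-preserving C1 profile with
  zero tilt at both apices and at the curve edges and three extreme tilts:
  one above the MT apex, one at the shared *transitional* vertebra between
  the apices, one below the TL/L apex.  Sharing the transitional tilt is
  what couples adjacent curves clinically (their common end vertebra), and
  the asymmetric split keeps every cohort combination of MT and TL/L
  magnitudes realizable — a symmetric-bump model cannot measure an MT curve
  smaller than half the TL/L curve.  The extreme tilts are refined by
  fixed-point iteration against the package's own Cobb measurement so the
  generated anatomy *measures back* the requested angles within 1°.
* **Sagittal** — a shape-preserving spline through kyphosis/lordosis
  control tilts at T1/T4/T12/L1/L5; kyphosis is measured T4–T12 and
  lordosis L1–L5 (a documented package convention — the levels are not
  standardized in the bracing literature).
* **Axial** — rotation proportional to each coronal bump, scaled so the
  apex ± 1 mean hits the requested apical rotation.

Two generator choices matter downstream and were fixed once, on anatomical
grounds:

* **Compensated trunk.**  The centerline is sheared linearly in z so T1 is
  plumb over the superior endplate of L5, the usual compensated presentation
  of moderate AIS.  (Without this, the T1-alignment step of the brace
  workflow concentrates an artificial kink in the T1–T2 segment.)
* **Skin coupling.**  Skin rings are swept ellipses whose centres follow
  the spinal deviation with a gain of 0.9 — over the ribcage the surface
  essentially translates with the spine — with level-dependent radii
  (shoulders/waist/hips) scaled by trunk height.  Trunk mass defaults to
  27.5 kg (half of an adolescent's ~55 kg body mass); the paper trail for
  the cohort gives no masses or heights, so both are config-exposed.

What the generator does **not** emulate: rib hump asymmetry, detailed torso
surface relief, vertebral morphology variation, soft-tissue thickness
distributions.  Tests passing on these synthetic torsos therefore validate
the *method's mechanics and contracts*, not clinical accuracy on real scans.

## The reduced-order trunk model

The trunk is a deliberately small static FE system that preserves the load
cases and outputs of a full patient-specific model:

* **Spine** — 3D space-frame (beam) elements between vertebral centroids.
  Stiffness is given in load-deflection form: axial 300 N/mm and bending
  2 N·m/deg per disk (divided by the patient's flexibility factor).  The
  bending value sits at the scale of functional-spinal-unit experiments.
  The axial value is an *effective* trunk stiffness: a single centroid
  chain with fixed end conditions over-stiffens lateral straightening
  through the axial load path (arch action), because the load sharing of
  ribcage and abdomen and the postural accommodation of a real trunk are
  absent.  300 N/mm restores a realistic lateral compliance at the apex
  (~3 N/mm, i.e. tens of newtons per centimetre of correction).
* **Vertebrae** — quasi-rigid beam offsets to the two pedicle nodes
  (200 × disk stiffness).
* **Soft tissue** — each skin node couples to its vertebra's rigid-body
  motion through an isotropic spring (axial 30 N/mm per level shared across
  the ring, transverse 30 %, thoracic levels ×3 for the ribcage); the
  rigid-offset coupling makes skin loads exert moments on the vertebrae.
* **Skin membrane** — truss springs between ring neighbours (2 N/mm) and
  between rings (1 N/mm).
* **Contact** — node-to-surface penalty springs, 0.008 N/mm per mm² of
  tributary area (~10 N/mm per node at default resolution), against the
  brace (a bilinear `rho(z, phi)` height-field on the skin lattice) and a
  unilateral mattress plane (polyurethane foam, E = 0.3 MPa over a 100 mm
  reference depth).

Solves are linear and incremental: loads ramp over the increments, the
contact set is re-linearized each pass, and an adaptive under-relaxation
damps active-set limit cycles.  Brace donning is smoothed by inflating the
shell by the initial interference and shrinking it across the increments.
The converged equilibrium residual is required to be below 10⁻⁶ of the
applied load.

**Standing calibration** finds the zero-stress state by reverse-gravity
fixed-point updates while muscle forces (antero-posterior and lateral at
T6, T10, L3, bounded ±200 N) are fitted by least squares so the loaded
spine reproduces the presenting geometry within 2 mm RMS.

**Growth-plate stresses** are recovered from the disk beam's internal
forces as `sigma = N/A ± M·c/I` on an elliptical endplate section
(semi-axes 15 × 20 mm), compression negative.  Under gravity every plate is
compressive and, on a convex-right curve, the concave (left) side is more
compressed — the Hueter–Volkmann precondition.

## Growth simulation

Treatment-average stresses combine the standing and in-brace fields with
the nightly compliance fraction `C = 0.33` (8 h/day).  Local growth rates
follow `G = G_m (1 + β (σ_side − σ_m))` with `G_m` 0.8 (thoracic) / 1.1
(lumbar) mm/year and `β = 1.5 MPa⁻¹`; negative rates (resorption) are kept
as the law prints them, with an optional floor at zero.  Growth is applied
*kinematically*: each vertebra gains the mean height and a coronal wedge
`atan(ΔG·Δt / width)` per plate, the wedges are accumulated up the stack,
the anatomy is rebuilt, and the standing configuration is re-calibrated and
re-solved on the grown spine.  This replaces the thermal-expansion elements
of solver-based implementations with a contract-equivalent geometric
update.

## Objective and constraint

Each simulated configuration is scored with
`phi = 2·(|MT ratio| + |TL/L ratio|) + 1·(sagittal terms) + 1·(AVR ratios)`
and the total is `OF = 5·phi_IB + 10·phi_PG`.  Sagittal terms measure the
deviation of the simulated kyphosis/lordosis from its documented normal
range (20–40° and 30–60°), normalized by the presenting deviation.  Two
guards make the score well-defined on the whole cohort: a simulated value
inside its normal range contributes exactly zero, and every denominator is
floored at 1° (patients presenting with normal sagittal alignment or zero
apical rotation would otherwise produce unbounded ratios).  Designs whose
peak nodal skin pressure reaches 450 kPa are infeasible: they enter the
surrogate with an additive penalty (10 × the initial-design score spread)
but can never become the incumbent.

## Surrogate optimization

The published algorithm description is qualitative (it used a packaged
implementation), so the concrete schedule here is fixed and config-exposed:

* initial design: 72 uniform random points plus the zero vector (the
  unmodified initial brace) as seed;
* surrogate: cubic RBF with a linear polynomial tail, refitted on all
  (deduplicated) evaluations each iteration;
* candidates: 500 Gaussian perturbations of the incumbent, each coordinate
  perturbed with probability `min(1, 20/36)`, standard deviation
  `scale × 50 mm`, clipped to the box; merit
  `w·(scaled surrogate) + (1−w)·(1 − scaled distance)` with `w` cycling
  0.3, 0.5, 0.8, 0.95;
* scale: starts at 0.2, halves after 3 × 36 consecutive non-improving
  iterations, counter resets on success;
* stopping: from iteration 500, stop when the best score improved < 5 %
  over the last 50 iterations; hard cap 1000.

On a 36-D quadratic bowl with the 573-evaluation budget this search
reliably lands within a fraction of a percent of the random-search baseline
median, and the suite asserts it beats equal-budget random search on five
seeds.

## Numerical choices and degenerate inputs

* Patch ordering is z-slow/phi-fast; `phi = 0` is anterior.
* Smoothing of the offset field is a separable Gaussian on the `(z, phi)`
  sites with bandwidths of half a patch; because the sites never move
  during optimization, the row-normalized weight matrix is precomputed
  once.
* The brace surface interpolator renormalizes partial lattice cells at trim
  and opening edges, keeping the contact field continuous (edge cells with
  less than half their corners present are off the shell).
* Straight spines: mirroring is the identity, the W-search returns W = 1
  with unchanged skin; a zero distortion threshold returns W = 0.
* End vertebrae, apices and curve signs are fixed on the presenting
  deformity and reused for all configurations, so in-brace and post-growth
  angles are comparable and over-correction shows as a negative Cobb.

## Problem sizes

The package's study sizes were chosen for a desk-scale demonstration: 16
skin nodes per ring (doubling to 32 changes the simulated Cobb by < 2°),
six load increments per in-brace solve, and a reduced optimization budget
of 73 initial + 77 adaptive evaluations (~150 in total) for the end-to-end
demonstration, versus 500–1000 iterations in a full clinical run.  A full
run is a configuration change, not a code change.

## Known limitations

* Linear kinematics: large-rotation effects (derotation under strap
  tension, rib-cage distortion) are outside the model.
* The brace shell is rigid in contact; strap tension acts as equal and
  opposite forces pulling the opening edges together rather than through a
  shell FE model.
* Growth is deterministic and uniform in time; no skeletal-maturity
  modulation, no viscoelasticity, no posture variation during sleep.
* The pressure constraint uses nodal tributary areas of a coarse lattice;
  real peak pressures concentrate on smaller areas.
* Clinical efficacy numbers from real cohorts (e.g. actual in-brace
  corrections measured on radiographs) cannot be reproduced from synthetic
  patients; the end-to-end demonstration checks the method's *hypothesis*
  (feasible brace, main-curve in-brace correction above 50 %, optimizer
  strictly improving on the initial brace) rather than cohort statistics.
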