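---
title: "Quantifying superimposition error in four-point plane orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying superimposition error in four-point plane orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourpoint)
```

## The model

Landmark-based superimposition of 3D craniofacial images expresses every
digitized point in an anatomical frame built from four cranial-base
landmarks. The frame construction is deterministic given one digitization
trial:

- y axis: unit vector from sella (S) toward nasion (Na) — anteroposterior,
  positive anterior;
- z axis: unit vector from basion (Ba) toward its perpendicular foot on the
  Na–S line — vertical, positive superior (orthogonal to y by
  construction);
- x axis: y × z — transverse, completing a right-handed triad;
- origin: MLWS, the midpoint between the posterior points of the bilateral
  lesser wings of the sphenoid.

Reorientation maps a point P to ((P−o)·x, (P−o)·y, (P−o)·z). The map is
rigid, so it preserves all inter-landmark distances, and it is equivariant
under global rigid motion of the inputs: two digitizations of the same
image land in a directly comparable frame regardless of how the patient was
positioned in the scanner.

The error analysis treats a *trial pair* — two digitizations of the same
image — as its unit. Four statistics are attached to each (pair, landmark):

- **Db**, the locating error: Euclidean distance between the two placements
  in scanner coordinates, with per-axis absolute differences;
- **Y**, the reorientation error: distance between the two positions after
  each trial is reoriented by its *own* frame. Since the reference
  landmarks are themselves relocated every trial, the two frames differ and
  Y compounds frame shift with the landmark's own Db. MLWS has Y ≡ 0 — it
  is each trial's origin;
- **DX**, the perpendicular distance of the pair-averaged landmark from the
  transverse axis of a frame built from the pair-averaged reference
  landmarks. DY, DZ and D0 (distances from the y and z axes and from the
  origin) are computed alongside as additional regression candidates;
- **A3r**, the sum (degrees) of the angles that the two placements of each
  of Na, S, Ba subtend at the averaged landmark — a landmark's-eye view of
  how much the reference configuration shifted.

Two modelling choices deserve note, both fixed and documented rather than
configurable: the averaged landmark and the A3r angles are computed in
scanner coordinates (both trials digitize the same image, and these
quantities are defined before/independently of reorientation); and DX uses
the averaged-reference frame applied to the averaged landmark rather than
averaging the two per-trial reoriented positions — the two constructions
differ only at second order in the noise. A3r is reported as `NA` for the
reference landmarks themselves: the two vectors from a reference landmark's
own average to its placements are antiparallel, making the angle
meaningless there.

Reliability uses ICC(3,1) — two-way mixed effects, single measurement,
consistency — computed per landmark per axis with patients as subjects and
the repeated trials as raters, matching a single observer re-digitizing
fixed images. Summaries report means, sample SDs (n−1) and quartiles by
inclusive linear interpolation (R's default type 7); quartile conventions
only affect the Q1/Q3 columns.

## The regression error model

One observation per (patient, pair, landmark) over the 15 non-reference
landmarks gives 300 rows per pair scope and 900 pooled. Responses more than
3 sample SDs from the scope mean are removed in a single pass (the rule is
applied to the response; a standardized-residual variant was considered and
rejected as harder to reproduce). Forward-entry/backward-removal stepwise
OLS then selects among the candidates {Db, DX, A3r, DY, DZ, D0} with entry
p < 0.05 and removal p > 0.10, the long-standing defaults of mainstream
statistics packages; both thresholds are arguments. VIF is computed as
1/(1−R²_j) per selected predictor. An intercept is always fitted and
reported, flagged as not comparable to published versions of the model that
omit it.

Numerical corner cases: a perfect fit (residual SD below 1e−8 of the
response SD) stops candidate entry — with zero residual variance further
p-values are numerically meaningless; a rank-deficient design within a step
(e.g. a duplicated candidate) raises a classed collinearity error rather
than silently dropping a column; stepwise with a single candidate
degenerates, intentionally, to significance-gated plain OLS.

On stepwise selection with null candidates: a candidate that is pure noise
still enters with probability ≈ the entry threshold once the true
predictors are in. With three decoys, the chance that *none* ever enters is
about (1−0.05)³ ≈ 0.86. Parameter-recovery simulations in the test suite
measure exactly this: the three true predictors are recovered in 100/100
replicates with coefficient bias below 10%, while the "no decoy selected
and every coefficient within 2 SE" event occurs in roughly 70–90% of
replicates, as the entry-threshold arithmetic dictates. This is a property
of stepwise selection itself, not of the implementation.

## The synthetic cohort

The generator emulates the study design: 20 patients, 3 digitization
trials of the same (virtual) image per patient, 19 landmarks.

- **Template.** A fixed skull template is expressed directly in the frame
  convention (MLWS at the origin, Na at (0, 72, 3), S at (0, 4, 3), Ba at
  (0, −12, −28) mm — midsagittal, anatomically plausible for an adult).
  Each of the 15 analysis landmarks is placed so its distance from the
  transverse axis equals the published per-landmark mean exactly; the split
  of that distance into anterior/posterior (y) and vertical (z) components,
  and the transverse offsets (±33 mm orbitale, ±55 mm porion, ±50 mm
  condylion, ±45 mm gonion), are not constrained by those distances and are
  fixed at plausible values. Bilateral landmarks mirror in x. Building the
  frame from the template and reorienting it reproduces the template — it
  is its own fixed point.
- **Placement noise.** Gaussian, independent across axes, landmarks and
  trials. Published calibration data are mean absolute per-axis differences
  m between two placements; if each placement has SD σ the difference has
  SD σ√2 and E|diff| = 2σ/√π, so σ = m·√π/2 reproduces m exactly in
  expectation. Anisotropy per landmark and axis is preserved (e.g. the
  orbitale x SDs are ~4× the condylion z SDs).
- **Between-patient variation.** Each patient's truth is the template
  scaled by Normal(1, 0.03), jittered per landmark by isotropic
  Normal(0, 2 mm), rotated by Normal(0, 5°) about a random axis and
  translated by Normal(0, 15 mm) per axis — size, shape and head-positioning
  scatter of plausible magnitude for adult craniofacial anatomy. These
  defaults make between-patient coordinate variance dominate placement
  noise by two orders of magnitude, which is what drives per-coordinate
  ICC above 0.99 (the qualitative finding the generator is meant to
  reproduce); they are assumptions, not estimates, and are configurable.
- All trials of a patient share the same truth (the same image digitized
  repeatedly); with zero noise the trials are identical and every error
  statistic is zero. Generation is deterministic per seed.

What the generator does *not* model — and therefore what passing tests do
not establish about real data: systematic digitization bias (an observer
consistently placing a landmark off-definition), voxelization and image
resolution, rater learning between sessions, and the real anatomical
covariance between landmark positions (the template jitter is independent
per landmark). In particular, the real data's regression coefficients
depend on the human error covariance structure, so the synthetic cohort
reproduces the *form* and qualitative behaviour of the error model, not
the published coefficient values; on synthetic cohorts the collinear
position-scale candidates (DX, DY, DZ, D0) are close substitutes and
scopes may select different members of that family.

## Problem sizes and determinism

The test suite works at the study's own scale (20 patients × 3 trials ×
19 landmarks; 900 pooled regression rows), enlarging only where a
statistical assertion needs it: 200 patients for noise-calibration checks,
10⁵ draws for Monte-Carlo identities, 100 replicates for
parameter-recovery, 1000 random configurations for the geometric
invariants (orthonormality, right-handedness, rigidity and equivariance to
1e−9). Geometric degeneracy (coincident Na/S, basion on the Na–S line) is
refused at 1e−6 mm, far below digitization noise and far above
double-precision rounding. All randomness flows through explicit seeds.

## Limitations

The regression pools the three pairs of each patient–landmark as
independent observations, mirroring the study design; a mixed-effects model
acknowledging patient clustering would be the natural extension. The
exclusion rule is single-pass by design; iterating it changes the kept set
only marginally but would change n. No inter-rater design is supported
(single-observer repeated measures only), and no alternative
superimposition methods (surface- or voxel-based) are implemented.
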