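---
title: "Measuring femoral anteversion from the anterior wall of the greater trochanter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoral anteversion from the anterior wall of the greater trochanter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femora)
```

## The measurement problem

The femoral anteversion angle (FA) — the axial-plane angle between the
femoral neck axis and the posterior condylar line — governs rotational
alignment in hip surgery, but measuring it requires imaging of the whole
femur. The anterior wall of the greater trochanter (GT) is exposed in many
surgical approaches, and its obliquity relative to the shaft (the
anterior-wall angle, AW) carries most of the rotational information of the
proximal femur. `femora` implements the full 3D measurement chain for
three angles on a triangulated femur surface:

* **FA** — angle between the femoral neck axis and the posterior condylar
  line, projected on the axial view; anteversion positive, retroversion
  negative.
* **NSA** (neck-shaft angle) — angle between neck and shaft axes on the
  anteroposterior (tabletop) view.
* **AW** — angle between the shaft axis and the tangent to the anterior
  wall of a simulated trochanteric cut surface, on the sagittal view of a
  femoral (ISB-style) anatomical frame; positive when the wall tips
  anteriorly going proximally.

It also provides the statistical layer that links AW to FA: a calibrated
cohort simulator, reliability machinery, and the forced-entry regression
that yields sex-specific prediction equations.

## Geometric pipeline

Given a surface mesh and a small set of named landmarks (lateral ridge of
the GT, a point at the base of the lesser trochanter, the two posterior
condylar points, the epicondylar midpoint, and optionally a hip-centre
hint), `measureFemur()` runs:

1. **Head centre** — least-squares sphere fit (`fitSphere()`): an
   algebraic linear solve initialises a Gauss–Newton refinement of the
   geometric residuals $|p_i - c| - r$.
2. **Shaft axis** — contour centroids of transverse sections at the base
   of the lesser trochanter and 50 mm further distally
   (`shaftAxis()`). For a circular (even obliquely cut) canal the section
   centroid lies exactly on the canal axis, so the choice of stacking
   direction does not bias the axis.
3. **Neck axis** — the line from the head centre through the centroid of
   the narrowest neck cross-section (`narrowestNeckSection()`). Cutting
   planes perpendicular to the current axis estimate are scanned in 0.5 mm
   steps starting 2 mm beyond the fitted head surface, with a 0.1 mm
   refinement pass around the area minimum; the axis is re-estimated from
   the recovered midpoint and the scan repeated until the midpoint moves
   under 0.1 mm (at most 10 iterations). The initial direction aims from
   the head centre at the shaft axis 15 mm distal to the lateral ridge —
   anatomically, the trochanteric fossa — and the procedure tolerates at
   least ±10° of initial-direction error.
4. **Trochanteric cut** — a plane through the point 5 mm distal to the
   lateral ridge, tilted about the anteroposterior axis until the resected
   cap's maximum thickness perpendicular to the plane is 10 mm (binary
   search, 0.1 mm tolerance; `simulateGtCut()`), reproducing the osteotomy
   level used clinically.
5. **Anterior wall line** — on the cut contour, the wall arc is seeded at
   the most anterior vertex and grown edge-by-edge while outward normals
   stay within 30° of the seed normal; a total-least-squares line is
   fitted and translated to the most anterior vertex (tangency;
   `anteriorWallLine()`). The arc must be at least 5 mm long.
6. **Frames and angles** — the tabletop frame is the scanner frame; the
   ISB-style frame takes its proximal axis from the epicondylar midpoint
   to the head centre and orthogonalises the intercondylar direction
   against it. All three angles are signed projections
   (`projectedAngle()`), so the whole measurement is invariant under
   rigid motion of mesh plus landmarks.

### Numerical and design choices

* **Wall-arc selection cone.** The cone is measured from the *seed
  normal* (the wall orientation at the most anterior vertex), not from the
  anterior axis. A cone fixed on the anterior axis would reject any wall
  more oblique than the cone half-angle, i.e. every AW above 30°, which
  real femora exceed; the seed-relative cone follows the wall wherever it
  points while still cutting the arc off at the contour's corners.
* **Neck-section tracking.** At each scan station the neck contour is the
  loop whose centroid continues the running centroid track (3 mm gate);
  the first station requires the loop to enclose the axis point. Selecting
  per-station minimum area instead is unstable: slivers clipped off the
  shaft rim or trochanter corners can present arbitrarily small areas.
* **Degenerate necks.** If the tracked area varies by less than 1% over
  the scan (a cylindrical "neck"), the mid-station centroid is returned
  and flagged `non_unique`.
* **Wall flatness.** The rms deviation of the wall arc from its fitted
  line is reported; above 0.3 mm the wall is flagged as not flat and the
  tangent at the apex is still returned (for a circular arc of
  femoral-head scale the rms is ~0.5 mm, so 0.3 mm separates genuinely
  flat walls from curved ones).
* **Axial-view convention.** Whether the axial view for FA is the scanner
  transverse plane or the plane perpendicular to the shaft axis is a
  modelling choice; the default is perpendicular to the shaft axis, a
  `axial_view = "tabletop"` switch selects the other, and the per-femur
  difference between the two is reported in the diagnostics rather than
  hidden.
* **Sign conventions.** Anteversion positive/retroversion negative; AW
  positive when the wall line tilts anteriorly going proximally, which
  makes AW and FA positively correlated; left femora are handled by
  detecting handedness from the landmarks, so a mirrored femur returns
  identical angle values with `side = "left"`.

## The phantom generator

CT reconstructions with known ground truth do not exist, so the package
tests itself on parametric phantoms (`buildPhantom()`): a union of
disjoint closed analytic shells — spherical head, neck of revolution with
a waist, vertical shaft cylinder (its axis is the canal-centre locus), a
GT block whose *anterior face plane makes exactly the dialled AW angle
with the shaft axis in the sagittal projection*, and two condylar bosses
whose most-posterior points define the condylar line. The neck axis
direction is built in closed form so that its axial projection makes
exactly the dialled FA with the condylar line and its AP projection
exactly the dialled NSA with the shaft axis. Ground truth is therefore
closed-form (`groundTruthAngles()`) and independent of triangulation; the
seed only drives optional vertex jitter.

Deliberate idealisations, and what they imply for validation: shells may
interpenetrate (each is individually watertight); the medullary canal is
represented by the outer shaft cylinder, whose section centroids coincide
with the true axis; the epicondylar midpoint is placed directly distal to
the head centre so the canonical ISB frame coincides with the scanner
frame; there is no cortical texture, no lesser-trochanter prominence
(its base level is a supplied landmark), and no osteonecrotic deformity.
Passing the phantom grid therefore demonstrates that the *geometry* of the
pipeline is correct to ±0.5° over the published anatomical ranges
(FA −12.1…38.4°, AW −0.5…42.5°, NSA 116.6…143.2°); it does not
demonstrate robustness to segmentation noise, cartilage, or pathological
shape, which only real CT data could.

Phantom default dimensions (head radius 24 mm, neck waist diameter 28 mm,
shaft radius 16 mm, shaft length 150 mm, GT height 35 mm) are typical
adult proximal-femur values; the three angle dials default to the
published cohort means (14.8°, 127.3°, 17.5°).

```{r}
ph <- buildPhantom(phantomSpec(mesh_resolution = "coarse"))
measureFemur(ph$mesh, ph$landmarks)
```

## The cohort simulator

`simulateCohort()` draws sex with 53% male hips, AW normal within sex
(male 14.6° ± 6.6°, female 20.8° ± 8.2°), FA from the linear model
`4.330 + 0.744·AW − 4.998·male` plus Gaussian residual, and NSA
independently normal (127.3° ± 5.4°) — independence mirroring the
observed near-zero FA–NSA correlation. The ONFH/normal label is assigned
independently of the angles, reflecting the observed null group
differences. Within-sex residual SDs are not published, so the residual
SD is derived from the pooled SD and fit R² as
`10.8·sqrt(1 − 0.507) = 7.58°` — an acknowledged approximation. Because
the published marginals imply an explained variance of ~53.3 deg², that
derivation gives a population R² of ~0.48 rather than 0.507;
`calibrateResidualSd()` instead chooses the residual SD that makes the
population R² hit a target exactly, and is what the reproduction script
uses for the fit-quality summary.

Retroversion arises naturally from the Gaussian tails (no special
mixture), and the simulator makes no attempt to model the mechanisms
that may decouple retroverted shafts from trochanteric morphology.

`simulateObservers()` emulates the two-observer, two-session reliability
design. Observer biases are *fixed* offsets ±δ calibrated from the target
interobserver ICC: with only two observers a randomly drawn bias is a
single-degree-of-freedom quantity and the realised ICC would wobble by
±0.05 regardless of cohort size; fixed offsets make the population ICC
identifiable, and the estimator recovers targets within 0.01 at
n = 2000. Session noise comes from the intraobserver target via
$\sigma_e^2 = \sigma_T^2 (1 - \mathrm{ICC}_{intra})/\mathrm{ICC}_{intra}$.

## Statistical layer

`olsForced()` is the forced-entry (all predictors entered, no selection)
least-squares fit via QR, reporting coefficients, standard errors,
standardized betas ($B \cdot s_x / s_y$), t-based p-values and 95% CIs,
the overall F with (2, n−3) degrees of freedom, adjusted R², the
Durbin–Watson ratio $d = \sum(e_i - e_{i-1})^2 / \sum e_i^2$, and flags
for |standardized residual| > 3. The intraclass correlation
(`iccEstimate()`) defaults to the two-way, absolute-agreement,
single-measures form — the standard choice for a two-rater design — with
a consistency flavor available; group comparisons default to Welch's t
(Student available), since the comparison test is otherwise
under-specified in clinical reporting. Display equations round half away
from zero at one decimal (so a male intercept of 4.330 − 4.998 = −0.668
prints as −0.7), while predictions default to full precision; the
display-rounded equations can shift a prediction by up to
$|0.744 - 0.7| \cdot 45 + 0.032 \approx 2.0°$ at the top of the AW range,
which is why `predictFa()` keeps both forms. The "error > 10°" fraction
uses the rounded equations (the form a surgeon would apply) and a strict
inequality.

Quantities that depend on the original CT cohort — the observed 17/100
hips with prediction error above 10°, r = 0.67, the group p-values —
cannot be recomputed from first principles here; the package reproduces
their output formats and their distributional analogues (e.g. the
Gaussian-tail exceedance $2(1-\Phi(10/\sigma_{res}))$) only.

```{r}
co <- simulateCohort(cohortParams(seed = 1))
fit <- olsForced(co$fa, co$aw, co$sex_code)
fit
makePredictionModel(fit)
```

## Problem sizes and reproducibility

The shipped tests measure the full 6 × 5 × 3 phantom grid at coarse
resolution (≈13 000 triangles per phantom, ~2 s per femur), check
rigid-motion invariance on a random subset, and use 500 simulated
cohorts of n = 100 for regression recovery — sizes at which every check
is Monte-Carlo stable except the mean sex coefficient, whose
Monte-Carlo SE at 500 cohorts is ≈0.07°. All randomness is seeded; a
phantom spec plus seed reproduces byte-identical meshes, and
`runEndToEnd()` records the seed and a configuration hash in every
results bundle.

## Known limitations

* The phantom's "lateral ridge" is a constructed edge point; on real
  femora the ridge is a rounded structure and the landmark is an input,
  not detected.
* Whether AW is constant along the GT wall is unknown; the cut level is
  fixed by the 5 mm / 10 mm rule, and `simulateGtCut()` plus
  `anteriorWallLine()` can be re-run at other entry points to explore
  level dependence, but the package asserts nothing about it.
* The ISB frame uses head centre, epicondylar midpoint and condylar
  landmarks only; frame sensitivity is surfaced through the axial-view
  diagnostic rather than resolved.
* No DICOM/voxel ingestion, no segmentation, no soft tissue; meshes and
  landmarks are the interface.
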