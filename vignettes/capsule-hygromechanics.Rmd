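---
title: "Modelling graded hygroscopic bending in seed-capsule walls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling graded hygroscopic bending in seed-capsule walls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hygrolam)
```

## The physical picture

A sesame capsule locule wall is a three-ply biological composite. From
the seed cavity outward it carries a transverse-fiber ply, a
longitudinal-fiber ply, and a thick soft mesocarp of parenchyma. The
fiber cells have their cellulose microfibrils nearly parallel to the
cell axis (measured angles sit around 8–12°), which makes each ply stiff
along its fibers and compliant across them; the parenchyma is a
foam-like, quasi-isotropic tissue. On drying, the parenchyma shrinks
dramatically — to roughly a third of its wet thickness — while the
lignified fiber plies barely change dimension. A shrinking skin bonded
to a stiff substrate bends the composite, exactly as in a bimetal strip,
and each fiber ply resists bending along its own fiber direction.

What makes the capsule interesting is that the three thickness fractions
change *gradually around the locule circumference*: a pure
longitudinal-fiber monolayer at the split region, increasing parenchyma
and transverse fibers toward the vascular bundle (where longitudinal
fibers disappear), and a return to mostly longitudinal tissue beyond it.
Because the local laminate differs at every circumferential station, so
does the local bending curvature, and the wall opens with a graded,
position-dependent movement rather than a single uniform curl.

## The laminate model

`hygrolam` realizes this as classical laminate plate theory (CLT) with
hygroscopic load resultants. Each station's stack is built by
`station_laminate()`: thicknesses `(X_T, X_L, X_M) * h_total` inner to
outer, fiber orientations 90° and 0°, and a free in-plane hygroscopic
strain ε on the parenchyma only. `solve_free_hygro()` assembles the ABD
system and solves

$$\begin{pmatrix} A & B \\ B & D \end{pmatrix}
  \begin{pmatrix} \varepsilon^0 \\ \kappa \end{pmatrix} =
  \begin{pmatrix} N^h \\ M^h \end{pmatrix}$$

for the traction-free deformation. The longitudinal curvature
$\kappa_x = \kappa_L$ is the model's output; $\kappa_y$ (the transverse
curvature) is carried along as a secondary quantity.

Assumptions worth stating explicitly:

* **End states only.** The model maps a fully wet to a fully dry state;
  there is no moisture-diffusion kinetics and no geometric nonlinearity.
* **One plate solve, not a shell.** The two bending directions come out
  of a single flat-plate solve. The real locule is a curved shell whose
  longitudinal and transverse curvatures interact; treating the
  directions as independent outputs of one laminate solve is the
  simplification that makes a closed-form analysis possible. We report
  $\kappa_x$ as the prediction and treat $\kappa_y$ as qualitative.
* **Only the parenchyma is hygroscopically active.** Fiber-layer free
  strain is set to exactly zero. This is deliberate: the interesting
  claim is that graded layer *thicknesses* alone, with a single active
  layer, reproduce the graded movement.
* **Relative units throughout.** Moduli enter as ratios (defaults
  20 : 5 : 0.1), the wall thickness is normalized to 1, and curvature
  profiles are normalized by their maximum. By linearity of the solve,
  scaling ε rescales every curvature identically, so none of the
  normalized predictions depend on the absolute value of ε, of the
  moduli, or of the wall thickness.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| stiffness triplet | (20, 5, 0.1) | relative | fibril-dominated along fibers, matrix-dominated across, soft foam parenchyma; typical for lignified plant composites |
| `nu` | 0.3 | – | generic soft-biocomposite value; unstated for this tissue |
| `G12` | `E_perp / (2 (1 + nu))` | relative | isotropic relation applied to the matrix-dominated direction |
| `eps_parenchyma` | −0.7 | – | isotropic in-plane shrinkage consistent with drying to ~30 % of wet thickness |
| `h_total` | 1 | – | wall thickness held constant around the circumference |

Poisson ratio and shear modulus are not reported quantities for these
tissues, so the defaults are generic. They matter little: the normalized
curvature profile is insensitive at the qualitative level, which you can
check directly —

```{r, eval = FALSE}
peaks <- sapply(c(0.2, 0.3, 0.4), function(nu) {
  peak_location(predict_curvature_profile(canonical_profile(),
                                          model_params(nu = nu)))
})
```

— the peak station does not move across this sweep.

The sign convention: curvatures are reported with positive $\kappa_x$
meaning the stack bends concave toward its outer (last-listed) surface.
A drying wall, whose shrinking parenchyma is outermost, therefore has
$\kappa_L > 0$: segments bend outward. Internally the standard CLT
system is solved with z running from the inner surface outward and the
solved curvature vector negated; the convention is pinned down by the
signed bimetal-strip formula (`timoshenko_bilayer_curvature()`), which
the plate solve reproduces to 1e-6 relative across two decades of
thickness and stiffness ratios whenever the two layers share a Poisson
ratio (equal ν keeps the biaxial-modulus ratio equal to the uniaxial
one, which is why the beam formula transfers to the plate exactly).

## What the synthetic generators emulate

The study's raw material — micrographs, dissected segments, polarized
light maps — is not distributable, so every input is generated with
known ground truth.

**Thickness profiles.** `canonical_profile()` interpolates knot values
of (X_M, X_L, X_T) at four anatomical anchors (split region s = 0,
mid-arc, vascular bundle s = 0.75, far side s = 1) with a monotone
shape-preserving spline (Fritsch–Carlson), renormalizes each station to
sum to 1, and adds seeded station-level jitter (sd 0.005, re-normalized).
The knots are *fixture calibration, not measured data*: they were chosen
once so the generated profile satisfies every qualitative feature of the
real architecture — longitudinal monolayer at the split (X_L ≥ 0.85),
X_L minimum inside s ∈ [0.7, 0.8] with parenchyma + transverse fibers
dominating there, mostly longitudinal tissue at the far side — and
reproduces the observed strength of the thickness correlations
(R²(X_M, X_L) ≈ 0.96 negative, R²(X_M, X_T) ≈ 0.5). The jitter standard
deviation is likewise a fixture choice representing station-level
measurement scatter.

**Segment arcs.** `arcs_from_profile()` inverts the dissection
measurement: equal-width segments, curvature interpolated at segment
midpoints, points emitted along exact circular arcs, an arbitrary rigid
motion per segment (a circle fit must not care), and optional Gaussian
coordinate noise. Noiseless generation followed by
`measure_curvature_profile()` reproduces the input normalized profile to
1e-6 — the round-trip oracle for the whole measurement chain.

**Azimuth maps.** `azimuth_fixture()` lays rectangular fiber-cell masks
at varied cell-axis angles on a dark background; inside a cell the
azimuth is the cell axis plus the true MFA plus von Mises noise, and the
retardance is high (90–130 nm) against a near-zero background, mimicking
the weak birefringence of parenchyma. The packaged truths are 8°
(transverse cells) and 12° (longitudinal cells).

**Shrinkage tables.** `shrinkage_fixture()` draws lognormal wet
thicknesses and scales them by the true ratio (default 0.30) with 2 %
multiplicative noise.

What the generators do **not** emulate: real section geometry (cell
boundaries, layer waviness), spatially correlated digitization error,
retardance-azimuth coupling, and segmentation error in the masks. A
passing recovery test therefore shows the *estimators* are correct and
unbiased under the stated noise model; it does not certify performance
on degraded real imagery.

## Numerical choices

* **Circle fitting** uses the algebraic Kåsa solution as the starting
  point for a Gauss–Newton refinement of the geometric
  (orthogonal-distance) objective, with the radius profiled out as the
  mean center-to-point distance. It is deterministic for a fixed point
  order and exact on noise-free circles. Collinearity is decided before
  fitting: if the rms orthogonal deviation from the best line is below
  1e-7 of the data span, the segment is flagged straight and carries
  R = ∞, mapping to κ = 0. That is a result, not an error — the
  split-region segment genuinely barely bends. The same flag is the
  fallback if the algebraic system is singular or the refined radius
  exceeds 1e8 times the span.
* **MFA estimation** takes the `n_points = 3` highest-retardance pixels
  in a cell (strongest crystalline-cellulose signal; ties broken by grid
  order so the estimate is reproducible), folds each azimuth-minus-axis
  difference into [−90, 90), and returns the absolute circular mean.
  Circular statistics use angle doubling because the azimuth is
  180°-periodic. The absolute fold inflates estimates near 0° truth
  (with symmetric noise the absolute mean of a zero-mean quantity is
  positive); this boundary bias is quantified in the tests and is
  irrelevant at the measured 8–12° angles, which sit four-plus noise
  standard deviations from the fold.
* **Von Mises noise** is drawn with the Best–Fisher rejection sampler,
  batched for speed, with concentration 1/σ² (σ in radians).
* **Zero-thickness layers are dropped** when a station laminate is
  built, rather than kept at epsilon thickness, so the ABD system stays
  well conditioned; a station with no tissue at all is an error.
* **Ties in `peak_location()`** break toward the smallest s; an all-zero
  profile returns NA with a "no movement" warning rather than a
  fabricated peak.
* **Reference plane.** The midplane is the default ABD reference; the
  tests verify that any other reference changes only the
  strain/curvature bookkeeping, not the physical curvature.
* **Measured-vs-predicted comparison** interpolates linearly in s
  (segment midpoints and anatomical stations never coincide). The
  pipeline resamples the prediction onto the segment midpoints before
  comparing, so the noiseless round trip is exact rather than limited by
  inter-grid interpolation error. Segment positions use the midpoint
  convention `l_n − d_n / (2 Σ d)`; the end-point convention is
  available via `position = "end"`.
* **Normalization** uses signed curvature divided by the signed maximum.
  For the capsule stack drying gives all-positive κ_L, so this equals
  the absolute-value convention; profiles with genuinely negative
  curvature should be normalized by the user's preferred rule.

## Open design points, resolved

* The curvature peak is predicted where the endocarp reduces to a
  *transverse*-fiber monolayer (no longitudinal fibers left): with
  nothing stiff along the capsule axis at that station, longitudinal
  bending is unresisted and maximal. This is a mechanical consequence of
  the solve — the tests construct arbitrary profiles with an X_L → 0
  window and verify the peak falls inside it — not a hard-coded rule.
* Per-cell MFA measurements are averaged within a cell first, then
  across cells (circular mean both times); cohorts below five cells warn.
* Measured segment curvature is reported unsigned with a separate
  bending-direction flag, since a dissected segment's photograph does
  not fix an orientation.

## Problem sizes

The packaged study conditions are 20 stations per profile, 8–9 segments
per dissection with 25 points per trace, 5 cells × 3 measurements per
MFA cohort, and 20 wet/dry sample pairs. The validation suite uses 200
randomized stacks for the quadrature oracle, a 7 × 7 grid over
thickness/stiffness ratios for the bilayer oracle, 1000 replicate
cohorts for MFA bias, and 1000 noisy replicates for circle-fit radius
recovery; these sizes give Monte-Carlo standard errors comfortably below
the tolerances they are tested against.

## Known limitations

* Flat-plate kinematics: no shell coupling between the two bending
  directions, no large-deflection effects.
* The fracture that initiates opening (at the false septa between
  locules) is out of scope; the model describes post-fracture bending.
* Absolute curvatures require absolute ε and moduli, which the package
  deliberately does not claim; only normalized profiles are predictions.
* The MFA estimator is a transparent azimuth-difference procedure, not a
  reimplementation of any proprietary instrument software; it is
  validated by parameter recovery on synthetic maps.
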