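---
title: "Measuring conjunctival microvascular hemodynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conjunctival microvascular hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjflow)
```

## The measurement problem

The superficial microvasculature of the bulbar conjunctiva can be imaged
directly through a slit lamp: under green (540 nm) illumination,
hemoglobin absorbs strongly, so vessels appear as dark tubes on the bright
sclera, and the granular pattern of red-blood-cell columns and plasma gaps
moves visibly along each vessel. From a one-second sequence at 50 frames/s
and 1.25 µm/pixel, the pipeline extracts, per vessel: diameter D, axial
velocity V, and the derived descriptors V_s, Q, WSR, η and WSS. At cohort
level, descriptors are compared across stages of diabetic retinopathy
(C/NDR/NPDR/PDR) with random-intercept linear mixed models, since every
subject contributes many vessels.

This vignette records the models, the parameters that matter, and the
choices made where the design was genuinely open.

## The synthetic data generator, and what passing tests mean

No patient data ships with the package, so both halves of the pipeline are
validated against a generator with analytic ground truth.

**Image sequences** (`scene_spec()`, `render_sequence()`). Each vessel is
an inverted super-Gaussian tube, intensity
$I = B\,(1 - c\,e^{-\ln 2\,(2d/D)^4})$ across the section: the exponent 4
flattens the core (blood columns absorb almost uniformly) while keeping
the full width at half maximum *exactly* D, so FWHM diametry has an exact
target rather than a convention-dependent one. The axial texture is frozen
1-d Gaussian noise with a configurable correlation length (default 8 µm,
the scale of red-cell aggregates and plasma gaps), advected along the
centerline by linear interpolation at the true velocity; band slope in the
kymograph is therefore exact by construction. Degradations: whole-frame
translational jitter (eye motion), blink frames at 10% of the background
intensity (an unambiguous mean-intensity outlier), a planar illumination
ramp, additive Gaussian sensor noise — and *static scleral mottle*
(smoothed 2-d noise, default sd 5% of background, correlation ≈ 6 px).
The mottle is not cosmetic: real conjunctival fields always contain static
tissue structure, and it is what intensity-based registration locks onto.
A scene whose only content is moving blood makes registration ill-posed —
any registration algorithm will track the flow — so the generator's
default emulates the real situation.

What the generator does **not** emulate: optics (depth of field, spectral
response), vessel tortuosity and caliber variation along a vessel,
pulsatile velocity modulation, out-of-focus vessel layers, and specular
reflections. Passing tests therefore demonstrate correctness of the
algorithms under the stated image model, not clinical performance on real
eyes.

**Cohorts** (`cohort_spec()`, `simulate_cohort()`). Vessel-level values
follow exactly the model the inference assumes:
$y_{ij} = \mu_g + b_i + \varepsilon_{ij}$, $b_i \sim N(0, \sigma_b^2)$,
$\varepsilon_{ij} \sim N(0, \sigma_e^2)$. Defaults encode a four-group DR
staging cohort: 34/47/45/35 subjects; arteriolar diameters around 18 µm;
control velocity 0.70 mm/s with an NDR deficit of 0.16 mm/s; roughly 12
vessels per subject; covariate distributions (age, sex, race mix, MAP, HR,
HCT, HbA1c) with the group gradients typical of such cohorts (HCT falling
and HbA1c rising with DR severity). The variance split
$\sigma_b = 0.05\text{–}0.08$, $\sigma_e = 0.15\text{–}0.20$ mm/s for
velocity reproduces a total SD near 0.23 mm/s with a realistic
intra-subject correlation. An optional per-group slope couples V to D
($V = \mu_V + s/1000\,(D - \mu_D) + b_i + \varepsilon$) for testing the
slope analysis. SBP/DBP are derived from simulated MAP and pulse pressure
so that MAP = (SBP + 2 DBP)/3 holds identically.

## Registration

Screening thresholds (defaults; all in `pipeline_config()`):

- **blink**: robust z of frame mean intensity > 4, with the MAD floored at
  0.5% of the median intensity so that artifact-free sequences with tiny
  variance do not produce spurious outliers;
- **motion**: correlation with the previous valid frame < 0.4. Flow alone
  decorrelates consecutive frames to ≈ 0.6–0.9 in synthetic scenes, while
  a genuine saccade of tens of pixels drops the correlation near zero, so
  the threshold sits between those regimes;
- **illumination**: peak-to-peak amplitude of a least-squares planar fit
  > 20% of the median intensity.

The longest consecutive run of valid frames is kept (ties: earliest run).

Translation estimation deserves a note, because the obvious estimator
fails. Phase correlation whitens the spectrum, which weights all
frequencies equally — including the high frequencies carried by the
*moving* blood texture. In scenes dominated by a few vessels the estimator
then tracks the flow rather than the eye motion. `register()` instead uses
plain (unwhitened) cross-correlation of each frame against the evolving
time-averaged image: moving texture averages out of the mean image, so
only static structure correlates. Two such passes are followed by two
refinement passes in which pixels of high temporal variance (the moving
blood) are masked out of both frame and average entirely, removing the
residual along-vessel pull that the flowing texture exerts on frames far
from the temporal centre. Sub-pixel resolution comes from local DFT
upsampling (20×) of the correlation peak rather than a three-point
parabola, which is unreliable on the broad peaks produced by smooth
tissue texture. The translation-only motion model (no rotation/scaling)
reflects that eye motion over one second at this field size is dominantly
translational. The reference frame is the middle frame of the run, which
minimises the maximum shift. On jittered synthetic scenes the injected
translations are recovered to well under 0.5 px, and registering a
jittered static scene restores the per-pixel temporal noise to within 20%
of the injected sensor noise.

## Vessel morphology

**Frangi vesselness** is computed on the intensity-inverted average at 8
log-spaced Gaussian scales, σ = 1–30 px, covering ridge half-widths for
6–75 µm vessels at 1.25 µm/px; β = 0.5. The structureness scale c is set
to half the maximum Hessian norm *globally across scales* (not per scale:
per-scale normalisation lets faint small-scale texture saturate its own
scale) and that maximum is taken over the border-trimmed interior, because
image edges produce spuriously strong large-scale responses. The mask is
vesselness above Otsu's threshold on the nonzero values, minus components
smaller than 50 px.

**Centerlines**: Zhang–Suen thinning preserves 8-connected topology;
terminal spurs reaching a bifurcation within 20 px are pruned (thinning a
wide tube leaves such spurs at blunt ends, and they would otherwise cut
the true centerline). Bifurcations are skeleton pixels with ≥ 3 neighbors;
the skeleton is cut there, each remaining component is traced into an
ordered path, and arc length is the sum of 1/√2-px steps times the pixel
size. Segments of length ≤ 50 µm are discarded — the strict reading of the
sampling-reliability rule. Station spacing for diametry is 5 px along the
*resampled* centerline (the raw skeleton's 8-connected steps are not
evenly spaced).

**FWHM diametry**: at each station the profile is sampled perpendicular to
a tangent obtained from a 7-point local quadratic fit, at 0.5-px steps
over ±60 µm; the background is the median of the outer 25% of the profile;
the diameter is the distance between the two half-maximum crossings found
by linear interpolation from the central peak outward. Stations without
two crossings are dropped; fewer than 3 valid stations rejects the
segment. On synthetic vessels the mean absolute error is well under 1 px
across 6–60 µm, including at 5% noise.

**Flow detection**: a segment is flow-detected when the mean temporal
intensity variance along its centerline exceeds twice the background
variance (non-vessel pixels inside the registration mask). The factor 2
keeps false detections on pure-noise scenes at or below the 5% level in
Monte-Carlo checks.

**Arteriole/venule labels** are annotations, not classifier output: in
real use they come from visual inspection of flow direction (divergence
into branches = arteriole, collection = venule); in synthetic mode they
come from the scene ground truth. Unlabeled vessels are excluded from
type-stratified statistics.

## Velocimetry

The spatio-temporal image S(s, t) samples each registered frame along the
centerline at 1-px arc steps (bilinear interpolation); rows and columns
are mean-subtracted so static structure — the vessel itself — drops out.
Band slope is found by a Radon-style orientation search: shear the STI by
a candidate slope m, average along lines, and score by the one-way
variance ratio (between-line over within-line mean square). The ratio form
matters: a raw projection-variance criterion is inflated wherever lines
collect only one or two samples, i.e. at extreme shears. Lines with under
~3 samples are excluded, which also sets the measurable-slope ceiling
|m| ≤ (stations − 1)/3 — every band must be seen in at least three frames.

The score peaks very sharply in m (width ≈ texture correlation length /
frame count ≈ 0.1 px/frame here), far below any practical uniform-angle
grid at steep slopes, so the search is hierarchical: a coarse 0.25-px/frame
slope scan on a short central window of 8 frames (few frames → wide peak),
then two refinement passes (0.05 and 0.005 px/frame) on the full STI with
parabolic interpolation. Velocity is |m| · (arc step) / (frame interval),
reported as a magnitude; the sign stays available for flow-direction
annotation. A quality score, (max − median)/median of the criterion over a
global reference grid, flags unreliable estimates below a floor of 2:
white-noise STIs score ≈ 0.2–0.8, real bands score in the tens to
thousands, so the floor separates the regimes by a wide margin. Across
0.1–3.0 mm/s (band slopes 1.6–48 px/frame) recovery on synthetic scenes is
within a fraction of a percent; an independent frame-to-frame
cross-correlation estimator serves as the oracle in tests.

## Hemodynamics

Conversions use the units of the clinical tables (D µm, V mm/s, Q pl/s,
WSR s⁻¹, WSS dyne/cm²):
V_s = V/k with k = 1.6, the conventional axial-to-mean conversion for
microvessels with blunted (non-parabolic) profiles — exposed as a
parameter because it is a modelling convention, not a measurement;
Q = V_s πD²/4; WSR = 8V_s/D; WSS = η·WSR with η from the in-vitro
diameter-dependent relative-viscosity law (Pries-type, capturing the
Fåhræus–Lindqvist effect) at the subject's hematocrit, with plasma
viscosity 1.2 mPa·s. The law's constants are configurable so an
alternative viscosity model can be swapped in; at the reference hematocrit
0.45 the relative viscosity collapses to
η*₀.₄₅(D) = 220e^(−1.3D) + 3.2 − 2.44e^(−0.06·D^0.645) (≈ 1.587 at
D = 20 µm), which the tests pin down to 10⁻¹².

Vessel identity for de-duplication is the connected component of the
skeleton before bifurcation cutting: segments cut from one component are
measurements along the same vessel, and only the longest centerline is
kept (ties: more diametry stations, then lower segment id). Subject-level
HCT is used for every vessel of a subject; no per-vessel hematocrit is
estimated.

## Cohort statistics

Two granularities, on purpose. ANOVA compares per-subject mean descriptors
(one value per subject), which is the simple stratified comparison; the
mixed models work on vessel-level rows with a Gaussian random intercept
per subject, which uses all measurements while respecting their
correlation. Estimation is REML via lme4 with Wald 95% CIs and two-sided
P-values at the 0.05 threshold — the estimator and interval type are this
package's documented choice (profile or Kenward–Roger intervals would be
defensible alternatives; Wald is standard at these sample sizes).
Group C is always the reference level; race is coded with the largest
category as reference (a deterministic default, since no natural reference
exists). The adjusted models add age, race, sex, MAP, HR, HCT, HbA1c as
fixed effects; rows with missing covariates are dropped and counted. If no
subject has repeated vessels the random intercept is unidentifiable and
the fit falls back to OLS with a warning. No multiple-testing correction
is applied — results are raw two-sided P-values.

Velocity-on-diameter slopes come from V ~ D × group + (1 | subject);
per-group slope = base + interaction, scaled by 1000 to s⁻¹ (mm/s per µm);
the comparison-to-control P-value is the Wald test of the interaction.
Calibration checks in the test suite: type-I error 5% ± 2% and CI coverage
95% ± 3% over 500 simulated null cohorts, and recovery of an injected
−0.16 mm/s NDR effect with |bias| < 0.02 mm/s over 200 replicates.

## Numerical and scale choices

Problem sizes in the tests and analysis scripts are chosen to exercise
every code path at desk scale: fields of roughly 250–400 × 150–550 px
rather than the full 1360 × 550 acquisition, 4–8 synthetic subjects with
4–10 vessels each for end-to-end runs, and 200–500 Monte-Carlo replicates
for inference calibration. All randomness flows from explicit seeds;
rendering, processing and statistics are bit-reproducible given seed and
configuration, and the pipeline writes a provenance record (config hash,
seed, package version) beside its outputs.

Degenerate inputs are handled explicitly: empty masks give zero segments
(with a warning); an all-invalid frame set, an all-zero STI, a constant
diameter column, or a single group each raise a named error; a
zero-variance profile rejects its station; ties in run selection and
de-duplication have documented deterministic tie-breaks.

## Known limitations

- The velocity ceiling scales with segment length (slope ≤ (stations−1)/3
  px/frame): fast flow in short vessels is flagged, not measured. At 50
  fps, 3 mm/s needs ≥ 145 stations (≈ 180 µm of usable centerline).
- Velocities are time-averages over the retained run; acquisition is not
  cardiac-gated, so arteriolar values sample unknown cardiac phases.
- The arteriole/venule distinction is manual by design.
- Frangi + Otsu segmentation assumes vessels darker than a locally bright
  background; pigmented or vignetted fields would need the threshold and
  illumination screening retuned.
- The viscosity and profile-factor constants are literature conventions;
  absolute WSS values inherit their uncertainty even where D and V are
  exact.
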