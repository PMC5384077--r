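# conjflow

Quantitative hemodynamics of the conjunctival microcirculation from
non-invasive slit-lamp image sequences.

The bulbar conjunctiva is the one place on the body where a microvascular
bed can be imaged directly, without contrast agents, through a slit-lamp
biomicroscope. A one-second sequence (50 frames/s, 1.25 µm/pixel, vessels
dark under 540 nm illumination) captures red blood cells streaming through
arterioles and venules of 6–75 µm diameter. `conjflow` turns such sequences
into per-vessel physiology and group-level statistics:

1. **Frame screening & registration** — blink, motion and illumination
   artifacts are rejected (robust z-score on frame means, frame-to-frame
   correlation, planar-fit gradient); the longest consecutive clean run is
   registered by sub-pixel whole-frame translation against the evolving
   time-averaged image, with moving (flowing) pixels masked out of the
   final refinement so the estimator locks onto static tissue.
2. **Vessel morphology** — multiscale Frangi vesselness on the inverted
   time-average, Otsu threshold, Zhang–Suen thinning, spur pruning,
   bifurcation cutting; segments with centerline length ≤ 50 µm are
   discarded. Diameter is the full width at half maximum (FWHM) of
   background-subtracted intensity profiles sampled perpendicular to the
   centerline every 5 px.
3. **Velocimetry** — a spatio-temporal image (kymograph) is built along
   each flow-detected centerline; axial velocity comes from the slope of
   its bands, found by a Radon-style orientation search (projection
   variance-ratio criterion with hierarchical slope refinement).
4. **Hemodynamics** — per vessel:

   | quantity | formula | units |
   |---|---|---|
   | cross-sectional velocity | V_s = V / k (k = 1.6) | mm/s |
   | blood flow | Q = V_s π D² / 4 | pl/s |
   | wall shear rate | WSR = 8 V_s / D | s⁻¹ |
   | viscosity | η = η_plasma · η_rel(D, HCT) (in-vitro Pries-type law) | mPa·s |
   | wall shear stress | WSS = η · WSR | dyne/cm² |

   When several segments are measured along one vessel, only the longest
   centerline is kept.
5. **Cohort statistics** — one value per descriptor per vessel per subject:
   ANOVA on per-subject means across DR stage groups (C/NDR/NPDR/PDR),
   random-intercept linear mixed models `y_ij = Xβ + b_i + ε_ij` (REML,
   Wald 95% CI; unadjusted, and adjusted for age, race, sex, MAP, HR, HCT,
   HbA1c), and per-group velocity-on-diameter slopes (in s⁻¹) with Wald
   comparisons to control.

Because no patient imaging data ships with the package, a synthetic module
generates (a) image sequences of dark tubes with an advected axial texture
of known velocity, plus jitter, blinks, illumination gradients, scleral
mottle and sensor noise, and (b) vessel-level cohorts with known group
effects, random intercepts and covariate distributions. Every stage is
tested against this ground truth.

## Worked example

```r
library(conjflow)

# a 20 um vessel with blood moving at 0.625 mm/s (= 10 px/frame here)
scene <- scene_spec(400, 140, vessels = list(
  vessel_spec(cbind(c(20, 380), c(70, 70)),
              diameter_um = 20, velocity_mm_s = 0.625)
), noise_sd = 0.02, jitter_amplitude_px = 1)
r <- render_sequence(scene, seed = 7)

reg  <- register(r$sequence, longest_valid_run(score_frame_quality(r$sequence)))
segs <- extract_centerlines(segment_vessels(reg$average), 1.25)$segments
seg  <- segs[[which.max(sapply(segs, function(s) s$length_um))]]
seg  <- measure_diameter(seg, reg$average, 1.25)
sti  <- estimate_band_slope(build_sti(reg, seg))

seg$diameter_um        # 20.885  (truth: 20 um)
sti$velocity_mm_s      # 0.6317  (truth: 0.625 mm/s, i.e. 10 px/frame)
vs <- cross_section_velocity(sti$velocity_mm_s, seg$diameter_um)  # 0.3948
blood_flow(vs, seg$diameter_um)                                   # 135.26 pl/s
wall_shear_rate(vs, seg$diameter_um)                              # 151.23 1/s
wall_shear_stress(blood_viscosity(0.45, seg$diameter_um),
                  wall_shear_rate(vs, seg$diameter_um))           # 2.915 dyne/cm2
```

These are the numbers the code prints for this scene: with sensor noise
and 1 px jitter present, the diameter is recovered within 0.9 µm of the
rendered truth and the velocity within 1.1% (the conversion is
slope × 1.25 µm/px × 50 fps).

The `analysis/` directory holds the narrative drivers, runnable in order
from the repository root after installing the package:

- `01_simulate_scenes.R` — synthetic imaging study (TIFFs + ground truth)
- `02_process_imaging.R` — full pipeline over those sequences, recovery vs truth
- `03_cohort_statistics.R` — four-group cohort simulation and the three
  table families (descriptor summaries, β/CI/P models, V-on-D slopes)
- `04_method_validation.R` — accuracy curves and inference calibration

Outputs land under `results/`.

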