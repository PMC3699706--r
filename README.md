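# smallheart

Quantification of left-ventricular (LV) volumes, ejection fraction (EF) and
diastolic filling indices from gated myocardial perfusion SPECT, with a
volume-dependent edge-shift correction for **small hearts** — ventricles
with end-systolic volume (ESV) ≤ 20 mL, in which partial-volume blurring
merges the opposing walls, shrinks the apparent cavity and inflates EF.
The package is aimed at nuclear-cardiology methods researchers who need a
fully inspectable, end-to-end testable implementation of such a chain, and
ships its own digital-phantom apparatus so volume recovery can be validated
without any external data.

## Method

1. **Delineation.** A closed heart-shaped surface (radii field on 12 axial
   levels × 24 angles, 6 apical cap sectors + pole, flat basal valve plane)
   is fitted to the first frame by iterating: sample count profiles
   perpendicular to the surface → place each node at the maximal-count
   position (3-point parabolic refinement) with a damped step → Laplacian
   smoothing → re-estimate centre/axis. Subsequent frames are fitted
   independently from the first-frame solution (no basal-motion
   constraint). Endo- and epicardial surfaces are defined **symmetrically**
   at ±`half_thickness` (default 5 mm) about this maximal-count
   mid-myocardial surface.
2. **Small-heart correction.** Both surfaces are shifted outward
   (epicardially) before volume computation by
   `s(v) = s₀ (1 − v/v₀)²` for `v ≤ v₀` (else 0), with `s₀ = 3.5 mm`,
   `v₀ = 85 mL`, where `v` is the frame's mid-ventricular volume (the
   volume enclosed by the pre-shift mid surface and the valve plane). The
   quadratic is the unique second-degree polynomial through
   `s(0) = s₀`, `s(v₀) = 0` with `s′(v₀) = 0` (a C¹, smooth transition).
3. **Function.** EDV/ESV/EF from the raw frame extrema
   (`EF = (EDV − ESV)/EDV`); a Fourier fit of the volume curve
   (fundamental to third harmonic) gives the analytic dV/dt curve and the
   diastolic indices PFR (max filling dV/dt ÷ EDV, s⁻¹), 1/3MFR (mean
   dV/dt over the first third of filling ÷ EDV), TPFR (end-systole to
   peak filling, ms) and TPFR/RR. Hearts are classed NH (ESV > 20 mL),
   SH20 (10–20 mL) or SH10 (≤ 10 mL).
4. **Validation apparatus.** A beating, breathing half-prolate-spheroid LV
   phantom with exactly known volumes; parallel-beam projection (32 views,
   180°), Poisson noise, OSEM (4 iterations × 8 subsets), 10 mm Gaussian
   post-filter, short-axis reorientation.

## Worked example

Simulate one virtual patient (true EDV 40 mL, EF 0.65 → ESV 14 mL), push it
through acquisition, reconstruction and quantification:

```r
library(smallheart)
spec   <- phantom_spec(true_edv = 40, true_ef = 0.65, rng_seed = 7)
result <- run_virtual_patient(spec)
result$quant
#> Corrected: <function_report> EDV 38.7 mL, ESV 12.0 mL, EF 68.9 %, class SH20
#>   PFR 1.87 /s, 1/3MFR 1.19 /s, TPFR 195 ms (TPFR/RR 0.195)
#> Uncorrected EDV 37.8 mL, ESV 7.9 mL, EF 79.1 %
```

Reading: the uncorrected fit recovers only ~56 % of the true ESV (7.9 of
14 mL) and overestimates EF by 14 EF points — the small-heart artefact.
The volume-dependent shift lifts ESV to ~86 % of truth and brings EF within
~4 points of the true 65 %. Per-frame detail (mid-ventricular volume,
applied shift, corrected/uncorrected volumes) is in `result$quant$frames`.

Curve-only analysis works directly from per-frame volumes:

```r
quantify_function(volume_curve(c(40, 33.5, 20.5, 14, 16.5, 23, 31, 37.5),
                               rr_ms = 1000))
#> <function_report> EDV 40.0 mL, ESV 14.0 mL, EF 65.0 %, class SH20
#>   PFR 1.63 /s, 1/3MFR 0.87 /s, TPFR 297 ms (TPFR/RR 0.297)
```

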