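# collarch

Quantitative image and biomechanics analysis for tissue-engineered tendon.

Cell-engineered tendon constructs are routinely characterised with a panel
of imaging and mechanical read-outs: label-free second-harmonic-generation
(SHG) microscopy of the collagen fibre network, confocal imaging of
collagen-probe-stained sections, transmission electron microscopy (TEM) of
fibril cross-sections, and uniaxial tensile testing. `collarch` implements
the full quantitative layer of that workflow as a tested, reusable R
package, together with a seeded synthetic-data generator so every stage can
be validated against known ground truth without laboratory data.

## What it computes

**GLCM texture curves (SHG images).** Pixel intensities are binned into
L = 20 grey levels and the grey-level co-occurrence matrix is accumulated
symmetrically for pixel pairs at 0°, 45°, 90° and 135° and distances
1..50 px (≈ 0–3.3 µm at 0.066 µm/px). From the normalised matrix
p(i, j) the four Haralick measures are computed:

- contrast  Σ (i−j)² p(i,j)
- correlation  Σ (i−µᵢ)(j−µⱼ) p(i,j) / (σᵢσⱼ)  (undefined → `NA`, never fabricated)
- energy  Σ p(i,j)²
- homogeneity  Σ p(i,j) / (1 + |i−j|)

Before feature extraction each image is rotated so the dominant fibre axis
(estimated from the global structure tensor) is vertical; the stated
outcome — GLCM correlation maximal at 90° — is verified post hoc.

**PLS-DA classification.** A from-scratch NIPALS PLS2 regression of the
autoscaled feature matrix against centred one-hot class indicators
(default A = 3 components), with argmax and nearest-score-centroid decision
rules and exact leave-one-out cross-validation (misclassification
granularity 1/n is always reported).

**Fibre orientation (structure tensor).** Gaussian-derivative gradients and
a Gaussian-windowed structure tensor give per-pixel orientation (0° =
vertical strain axis, range (−90°, 90°]), energy and coherence
(λ₁−λ₂)/(λ₁+λ₂). Orientations are binned into 2° histograms normalised to
percent, and an alignment percentage is reported as the mass within ±10°
of the mode.

**Fibril morphometry (TEM masks).** 8-connected components of a binary
cross-section mask; each profile's equal-second-moment ellipse (pixel
covariance with the +1/12 per-pixel correction, axes 4√λ) gives the
minimum (minor-axis) diameter used as the fibril-diameter proxy; exact
medians and fixed-width frequency distributions follow.

**Mechanics.** Engineering stress σ = F/A (A = πd²/4 from one projected
diameter, default d = 2.43 mm) and strain ε = Δl/l (default l = 8 mm);
maximum stress/strain; Young's modulus as the max-R² sliding-window slope
of the loading curve; hysteresis and percentage energy loss from
trapezoidal loading/unloading areas; stress-relaxation rate
(σ₀ − σ₆₀)/T over a T = 60 s hold.

**Synthetic data.** Fibre fields with axial von Mises orientations
(concentration κ), sinusoidal undulation and Gaussian cross-profiles;
non-overlapping elliptical fibril masks with lognormal minor diameters;
standard-linear-solid (SLS) load traces with closed-form expected
relaxation rates — all pure functions of (params, seed).

## Worked example

```r
library(collarch)

# a standard-linear-solid relaxation test: ramp to 10% strain, hold 90 s
res <- gen_sls_trace(sls_params(protocol = "ramp_hold", ramp_rate = 0.05,
                                tau = 20, hold_duration_s = 90))
mechanical_summary(res$trace, res$geometry)
#> Mechanical summary
#>   sigma_max: 7.855 kPa at strain 0.1000
#>   Young's modulus: 77.425 kPa (R^2 = 1.0000)
#>   relaxation rate: 0.04521 kPa/s over 60 s
res$expected$relax_rate_kPa_s   # closed-form oracle: 0.04521236

# orientation analysis of a synthetic aligned fibre field (kappa = 16)
img <- gen_fibre_image(fibre_field_params(image_size = 256, kappa = 16,
                                          n_fibres = 120, seed = 7))$image
oa <- orientation_analysis(img)
#> mode -1.0 deg, alignment 78.7%

# fibril morphometry of a synthetic TEM-like mask
fm <- gen_fibril_mask(fibril_field_params(image_size = 512, n_fibrils = 60,
                                          diameter_median_nm = 36.3, seed = 4))
diameter_distribution(fm$mask, pixel_size_nm = 1)
#> Fibril diameters: n = 60 retained (0 excluded), median 32.86 nm
```

The relaxation rate equals the SLS closed form to within sampling error;
the alignment mode sits at the generated mean orientation; the recovered
median tracks the sample median of the 60 lognormal draws (32.9 nm here —
the population median is 36.3 nm, and the estimate converges at larger n).

An end-to-end run (simulate four groups → align → GLCM profiles → PLS-DA
with LOO CV) is one call:

```r
run_pipeline(default_run_config(out_dir = "out", seed = 1, image_size = 256))
```

which writes `features.csv`, `scores.csv`, `report.json` (misclassification
rate, confusion table, per-sample predictions) and the resolved config.

## Command line

```sh
inst/scripts/collarch run      --out out --seed 1
inst/scripts/collarch simulate --what fibres --out sims --seed 1
inst/scripts/collarch texture  --in sims --out features.csv
inst/scripts/collarch classify --features features.csv --label-col group --out report.json
inst/scripts/collarch orient   --in sims/control_01.tif --out orient/
inst/scripts/collarch fibrils  --mask mask.tif --pixel-size-nm 1 --out fibrils/
inst/scripts/collarch mech     --trace trace.csv --l0-mm 8 --diameter-mm 2.43 --out mech.json
```

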