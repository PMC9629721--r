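---
title: "Methods: collagen architecture and biomechanics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen architecture and biomechanics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`collarch` re-implements, as one coherent package, the quantitative
analyses used to characterise tissue-engineered tendon constructs:
texture-based classification of SHG collagen images, structure-tensor
orientation mapping, TEM fibril morphometry and tensile/viscoelastic
mechanics, plus the synthetic generators that stand in for unreleased
laboratory data. This vignette records the models, the parameters that
matter, the numerical choices, and the places where the design was
genuinely open.

## 1. Texture analysis of fibre images

### Model

An image is quantized into `L = 20` grey levels by linear binning over its
own min–max range. For an angle $\theta \in \{0, 45, 90, 135\}^\circ$ and
distance $d$ pixels, the co-occurrence matrix counts quantized pairs at the
offset (rows increase downward): $0^\circ \to (0, d)$,
$45^\circ \to (-d, d)$, $90^\circ \to (-d, 0)$, $135^\circ \to (-d, -d)$.
Accumulation is symmetric (each unordered pair counted in both orders), so
$0^\circ$ and $180^\circ$ are equivalent and the matrix equals its
transpose exactly. From $p = \text{counts}/n_\text{pairs}$ the four
Haralick measures (contrast, correlation, energy, homogeneity) are
computed; a texture profile is the full
$4 \times 4 \times D$ grid over distances $1..D$ ($D = 50$ px $\approx$
3.3 µm at 0.066 µm/px), flattened measure-major for classification.

### Numerical choices

- **Binning range.** Per-image min–max. The binning range is not dictated
  by the measurement model; per-image range is the common microscopy
  default, is invariant to intensity offsets, and is recorded in
  `QuantizedImage$source_range` for audit. A constant image is flagged
  degenerate rather than quantized arbitrarily.
- **Undefined correlation.** If either marginal has zero variance the
  correlation is `NA` — an explicit undefined marker. Profile cells
  carrying `NA` in any image are dropped consistently across the dataset
  before classification (`texture_feature_matrix$dropped_features`), never
  silently replaced by 0 or 1.
- **Dominant-axis correction.** The published workflow rotates images so
  the dominant fibre axis is vertical (maximum GLCM correlation along the
  y-axis); the exact published algorithm is not reproducible from the text,
  so the correction here estimates the dominant orientation from the
  energy-weighted global structure tensor (in angle-doubled axial space),
  rotates by its negative with bilinear interpolation, and then *verifies
  the stated outcome*: correlation at 90° must exceed the other three
  angles at a reference distance (default 4 px). On verification failure or
  near-isotropy (mean coherence < 0.1) the unrotated image is returned
  with `anisotropy_flag` set.
- **Crop.** Rotated images are centrally cropped to the largest square
  valid under *any* rotation ($\lfloor N/\sqrt2 \rfloor$), so zero-padding
  never contaminates GLCM statistics and all aligned images share one
  geometry.

## 2. PLS-DA classification

NIPALS PLS2, written in-package rather than wrapped: $X$ is centred and
autoscaled (unit variance — GLCM measures live on scales that differ by
orders of magnitude), $Y$ is the centred one-hot indicator matrix, and
components are extracted with $X$-deflation; training scores are mutually
orthogonal to machine precision (a tested invariant). Constant features
are removed before scaling, and removed *again inside every
cross-validation fold*, with prediction-time alignment by feature name.

Two decision rules are provided:

- `max`: argmax of the predicted indicator values (the conventional
  PLS-DA read-out), the default of `predict()`;
- `centroid`: nearest class centroid in latent score space.

The end-to-end pipeline and its leave-one-out CV default to `centroid`.
The reason is structural: with $A = 3$ components and four classes the
rank-3 indicator regression cannot place four class targets freely, and
the argmax rule misclassifies a large fraction of borderline samples that
are perfectly separated in score space; the centroid rule uses the same
latent model but classifies where the separation actually lives. Both
rules are exercised by the tests.

Leave-one-out CV refits everything from scratch per fold and reports the
misclassification rate together with its granularity $1/n$ — with 16 CV
units one error is 6.25%, with 32 units it is 3.125%, so reported rates
are only meaningful alongside $n$.

## 3. Orientation analysis

Gaussian-derivative gradients (σ = 1 px) feed the structure tensor,
smoothed with a Gaussian window (σ = 4 px). Per pixel: the fibre
orientation is the direction of least intensity variation, mapped to the
strain-axis convention (0° = vertical, positive clockwise on screen, range
(−90°, 90°]); energy is the tensor trace; coherence is
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$, set to 0 at zero energy.

Histograms use 2° bins tiling (−90°, 90°], exclude pixels with coherence
below 0.1, weight the rest by gradient energy by default
(coherence-energy and unweighted modes are available — the reference
ImageJ tooling offers several and no single mode is canonical), and are
normalised to percent.

**Alignment percentage** is the mass within ±10° of the histogram mode
(mode-centred, i.e. "normalised to 0°", before any group comparison).
Bins partially covered by the window contribute fractionally, so the
statistic is continuous in the halfwidth and a uniform histogram yields
exactly $2 \times \text{halfwidth}/180$ (11.1% at the default 10°). The
halfwidth is a prominent, documented knob: published alignment
percentages come with no stated window, so cross-study values are
qualitative ordering targets only, and the tested claim here is
*monotonicity* — alignment strictly increases with the generator's
orientation concentration — not any printed percentage.

## 4. Fibril morphometry

Binary masks only: with real TEM micrographs the fibril outlines were
traced interactively, so the reproducible computation is the measurement
geometry, not grey-level segmentation. Components are labelled with
8-connectivity; profiles below 9 px area or touching the image border are
excluded from statistics (truncated profiles bias the minor axis
downward) but counted in `n_excluded`.

Each retained profile is summarised by its equal-second-moment ellipse:
eigenvalues $\lambda$ of the pixel-coordinate covariance (with the +1/12
per-pixel variance correction, so a single-file line of pixels has a
positive, flagged minor axis) give axes $4\sqrt{\lambda}$ — the ImageJ
"fit ellipse" convention under which a filled disc of radius $r$ measures
diameter $2r$. The *minor* axis is the fibril-diameter proxy: it is
insensitive to oblique sectioning, which elongates only the major axis.
Medians are exact sample medians; histograms use fixed 5 nm bins anchored
at 0.

## 5. Mechanics

Engineering definitions throughout, with the pre-load cross-section:
$\sigma = F/A$, $\varepsilon = \Delta l / l_0$ ($l_0$ = 8 mm by default),
$A = \pi d^2/4$ from a single projected diameter (default 2.43 mm) — the
circular-cross-section assumption is explicit in the output metadata.
Young's modulus is the OLS slope over the contiguous loading-phase window
(20% of points by default) maximising $R^2$; the selection rule is ours,
as none is published, and the chosen region and $R^2$ are always
reported. Hysteresis is the difference of trapezoidal areas under the
loading and unloading branches, each over its own samples; energy loss is
that difference as a percentage of the loading area. The stress-relaxation
rate is $(\sigma_0 - \sigma_T)/T$ with $T = 60$ s and $\sigma_T$ by linear
interpolation at exactly $t = T$ into the hold. Maximum strain defaults to
the strain at peak stress; a user-supplied rupture index overrides it,
since rupture criteria are protocol-specific.

## 6. The synthetic world, and what a green test establishes

The generators emulate the *statistical structure* of the real data, not
the physics of its acquisition:

- **Fibre fields.** Base orientations follow an axial von Mises law
  (sampled as $\varphi \sim \mathrm{vM}(2\mu, \kappa)$ on the circle,
  halved — the standard axial construction, sampler: Best–Fisher
  rejection). Fibres are sinusoidally undulating lines with Gaussian
  cross-profiles; intensities add and clip at 1; acquisition is emulated
  by additive Gaussian noise (σ = 0.02, standing in for 300-frame
  averaging, since downstream texture statistics depend on SNR, not on
  frame mechanics) and a 0.5 px Gaussian blur. The default image side is
  512 px (the published "5122 × 512" format, read as a typo for
  512 × 512 and configurable).
- **Group recipes.** The four default conditions (static control, 3%, 5%,
  10% cyclic strain) differ in κ (1, 4, 16, 64 — alignment rises with
  strain), fibre width (3.0 → 1.2 px — edges sharpen) and undulation
  amplitude (5 → 1 px — fibres straighten), eight images each. These are
  deliberately *well-separated* groups: the end-to-end test establishes
  that the pipeline recovers separable structure when it exists, not that
  real strain groups are this separable. Fibre count scales with the image
  side (120 at 256 px) so coverage is scale-invariant and small test
  images do not saturate.
- **Fibril masks.** Dart-thrown non-overlapping ellipses, lognormal minor
  diameters (medians configurable; defaults span the published
  33.8–40.2 nm range), uniform elongation up to 1.6; a conservative
  bounding-circle distance test enforces the minimum gap, and placement
  failure names the achievable count.
- **Load traces.** A standard linear solid (equilibrium spring $E_{eq}$
  parallel to a Maxwell arm $E_m$, $\eta$; $\tau = \eta/E_m$) sampled in
  closed form under ramp-hold and triangle protocols, with the closed-form
  expected relaxation rate
  $\sigma_{m}(t_1)(1 - e^{-T/\tau})/T$ attached to every trace as an
  oracle. Hysteresis and relaxation are genuine SLS behaviour, not noise.

What green tests do **not** establish: performance on real SHG/TEM images
(no optics, no detector noise model, no out-of-focus light, no cellular
autofluorescence); correctness of any published percentage measured on
unreleased specimens (those enter only as qualitative orderings); or
robustness of grey-level fibril segmentation (out of scope by design).

## 7. Known limitations

- The structure-tensor dominant angle wobbles by up to ~1° on wavy
  phantoms (finite sample of undulation phases); the ±2° contract on the
  dominant-axis correction absorbs this.
- The energy-weighted orientation histogram over-weights bright, saturated
  regions; heavily saturated renders can triple a uniform phantom's modal
  bin. The test phantom for the uniformity property therefore uses dense,
  low-intensity fibres, and real analyses should prefer unsaturated
  acquisitions (or the unweighted mode).
- LOO misclassification on 32 samples has granularity 3.125%; differences
  smaller than one CV unit are not resolvable.
- The TIFF codec is deliberately minimal (uncompressed, single-plane,
  8/16-bit greyscale); compressed or tiled TIFFs must be converted first.
- The von Mises sampler is a scalar rejection loop — fine for hundreds of
  fibres per image, not tuned for millions of draws.
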