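---
title: "retoct: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retoct: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retoct)
```

`retoct` quantifies retinal degeneration from OCT B-scans: layer
segmentation by shortest-path search, ROI morphometry around the optic
nerve head (ONH), attenuation-based reflectance (eAC), vitreous particle
counting, and time-course statistics. Because the package is validated
end-to-end on synthetic data, this vignette describes both the analysis
methods and the generative model, and is explicit about what a passing
test does and does not establish.

## 1. Coordinate and boundary conventions

Rows are depth (row 0-based index 0 = top of image, vitreous side),
columns are A-scans. A boundary value `b` is real-valued and 0-based: the
tissue transition lies between pixel rows `floor(b)` and `floor(b) + 1`.
A pixel row `r` (1-based in R) covers depth `[r-1, r)`, so the pixel set
of a layer between boundaries `b_up < b_low` is rows
`floor(b_up)+1 … floor(b_low)` (0-based). All generator configuration is
in micrometers and 1/m; conversion to pixels happens only at render time
(axial pitch 1.7 µm/px, lateral pitch 1.4 µm/A-scan, 1000 A-scans per
1.4 mm B-scan).

## 2. Segmentation

**Cost maps.** Boundaries are intensity transitions with a known polarity
(e.g. vitreous→NFL is dark-to-bright, RPE→choroid bright-to-dark). The
cost map is `1 − (max(s,0)/max(s))^p`, where `s` is the signed vertical
gradient of the Gaussian-smoothed image matched to the polarity and `p`
is a sharpening exponent.

**Shortest path.** For each boundary we find the exact minimum-total-cost
left-to-right path with `|Δrow| ≤ max_step` per A-scan by dynamic
programming (Rcpp); ties break toward the smaller row index so results
are deterministic. Exactness is property-tested against exhaustive path
enumeration on small grids.

**Anchor-first sequential banding.** After the surface, the *lower ONL
boundary* is located next: it is the most prominent dark-to-bright rise
below the surface in both schemas (ONL→IS+OS, or ONL→OR in degenerated
retina), searched in a wide band below the surface. The remaining
boundaries are then extracted top to bottom, each in a band *relative to
the previous boundary* offset by the plausible thickness range of the
intervening layer (generous ranges covering the whole time course and
per-eye severity spread, e.g. ONL 3–78 µm), and — for the inner
boundaries — capped from below by the anchor minus the minimum thickness
of the layers in between. The cap matters: in severely degenerated eyes
the outer retina thins until the bright ONL/OR rise falls inside the
INL/OPL search band and would otherwise capture it (found by validation on
high-severity phantoms). Banding enforces monotone ordering by
construction.

**Surface robustness.** Vitreous particles can be brighter than the
retina surface. A shared pre-pass estimates the surface with heavy
*lateral* smoothing (σ = 8 columns), which dilutes small blobs while the
laterally continuous surface edge survives; each variant then searches
boundary 1 within ±8 px of that estimate. An image with no plausible
surface (all-zero, constant, pure speckle) raises a segmentation-failure
error rather than returning a silent result.

**Segmenter variants ("models").** Neural-network segmentation is out of
scope; the model-ensembling workflow is preserved with five parameterized
variants of the classical segmenter (lateral smoothing σ 1–3, path
stiffness `max_step` 2–3, sharpening `p` 1–1.5). The variant σ acts
laterally, emulating A-scan averaging, with axial smoothing capped at
1.6 px: isotropic smoothing at σ ≥ 2.5 merges the edges of the ~6 px RPE
band and makes the path lock onto IS/OS substructure — a genuine design
lesson discovered during validation, documented here because the obvious
isotropic choice fails. The per-A-scan median of the variants
("Model_median") is the default segmentation; `usage_rate()` and
`dice_score()` quantify variant agreement, emulating the
select-the-best-fit review step.

**Sub-pixel refinement.** The DP row is refined by a parabolic fit to the
matched gradient; for a step edge rendered with area-weighted pixel
coverage, the vertex recovers the sub-pixel boundary exactly (estimate =
peak position − 0.5 in this package's conventions). This is what lets
200-A-scan ROI averages resolve a 0.5 µm RPE change at 1.7 µm/px.

**ONH masking.** Columns whose gradient energy falls below 30% of the
B-scan median, grown by 5 columns per side, are flagged invalid; the two
sides are segmented independently and all ROI statistics skip invalid
A-scans.

## 3. Morphometry

ROIs are 200 A-scans spanning 350–630 µm from the detected ONH center on
each side (`select_rois`), distances converted with the lateral pitch and
no curvature correction. Thickness is the ROI mean of
(lower − upper) × Δ using sub-pixel boundaries; an eye at a timepoint is
the unweighted mean of its 8 ROI values (4 B-scans × 2 ROIs), requiring
at least 4 (proportionally fewer in scaled-down designs). For
normal-schema days an `OR = IS+OS + RPE` value keeps the outer-retina
column comparable across the schema switch. The schema switch day is 6:
days 0–3 use the 9-boundary normal schema, days 6–20 the 8-boundary
degenerative schema; a bias check compares inner-layer thickness between
both schemas on the same image.

## 4. Reflectance (eAC) and Dip ratio

On the linear intensity scale, after subtracting a scalar background `N`
estimated from the particle-free vitreous (`I(z) = U(z) − N`, clamped at
0), the estimated attenuation coefficient is

µ̂[i] = I[i] / (2 Δ Σ_{j>i} I[j]),

with Δ in meters — the depth-resolved estimator under a
complete-attenuation boundary condition at the image bottom, with no
signal-decay factor. Conventions chosen here: `N` is a scalar per B-scan
(no depth model is published for it); pixels whose remaining tail energy
is below 10⁻³ of the A-scan total are masked; the bottom 5 image rows are
excluded from layer statistics to bound truncation bias; layer summaries
are means of log10 µ̂ (base 10 chosen for the conventional "logarithmic
scale"). The estimator is exactly scale-invariant per A-scan, which is
the basis of the shadow-compensation property.

Two estimator facts matter for interpretation. First, the closed form for
a uniform medium, (1−r)/(2Δr) with r = e^(−2µΔ), carries a +0.9%
discretization bias at µ = 5000 m⁻¹ and assumes an infinite tail;
accuracy statements therefore hold at depths with ≥ 300 px of remaining
tail. Second, the estimator is nearly blind to a pure attenuation change
in a thin dark layer (the tail below dominates the ratio). A tissue
reflectance change is a scattering change, so the generator co-moves
backscatter and attenuation for the degeneration effects (ONL elevation,
RPE reflectance loss); with attenuation alone the published ONL eAC
elevation would be unmeasurable by construction, which we judged a
modelling artifact rather than the intended world.

**Dip ratio.** Per A-scan in an ROI: the IS peak is the intensity maximum
in the upper half of the IS+OS band, the Dip the minimum between that
peak and the band's lower boundary; the ratio is mean(peak)/mean(dip).
The upper-half/lower-boundary windows are a documented convention (the
original definition does not fix them). Only defined for the normal
schema; degeneration fills in the dip, lowering the ratio.

## 5. Vitreous particles

Everything above boundary 1 is vitreous. The image is binarized at
mean + 4 SD of the particle-free vitreous background (Otsu fallback when
no background statistics exist — the original workflow's manual threshold
is not published), 8-connected components are labeled (Rcpp,
oracle-tested against brute-force label propagation), and components with
area in [5, 500] px (inclusive; units assumed pixels, configurable) are
counted.

## 6. Time-course statistics

- `fit_exp_decay`: least squares for T(t) = C + A·e^(−kt) via a k-grid on
  [0.01, 2] day⁻¹ with closed-form linear LS for (C, A), refined by
  golden-section search — global, deterministic, derivative-free. A floor
  term C is included because the reference thickness table plateaus near
  14–17 µm. Constant series are flagged not-identifiable.
- `linfit_r2`: OLS with R² = 1 − RSS/TSS (0 for constant y);
  case-resampling percentile bootstrap CI (default 2000 resamples,
  seeded; the CI method for the published values is unstated).
- `paired_t`: textbook paired t-test; all-zero differences give p = 1
  with a flag, zero-variance nonzero differences report p below the
  machine floor with a flag. No multiple-testing adjustment is applied
  (matching the original analysis); this is deliberate and documented.

## 7. The phantom generator: what it emulates, what it does not

Expected intensity in layer L at depth z is
`reflectivity_L · exp(−2 µ_cum(z))` plus an additive background; speckle
is fully developed (exponential), and n-frame averaging (default 40) is
emulated by a single Gamma(n, n) multiplicative factor per pixel —
matching first and second moments of averaged speckle without modelling
interferometry. Boundaries are real-valued with area-weighted pixel
coverage at transitions, so a uniform layer decays by exactly
e^(−2µΔ) per pixel and sub-pixel recovery is testable. The ONH is a
wedge where retinal boundaries converge onto the retina/choroid boundary
(width 90 px ≈ 126 µm); the IS+OS band has internal peak/dip/OS structure
so the Dip ratio is defined; particles are non-overlapping discs placed
above the (wedge-free) surface, laterally concentrated near the ONH,
Poisson counts following the per-day series.

The time course encodes the published group means: ONL follows
C + A·e^(−kt) with (C, A, k) = (18.1 µm, 44.5 µm, 0.227/day) fitted by
least squares to the six reference means (half-decay 3.05 days); inner
layers are piecewise-linear through the reference rows (INL/OPL swelling
peaking at day 3); RPE swells by 0.5 µm at days 1–3; IS+OS and RPE merge
into OR at day 6; the choroid thins monotonically from 88.6 µm; particle
counts peak at day 1 (≈ 40) and return to baseline (≈ 3) by day 13, which
is the published qualitative time course. Where the publication prints no
number (per-layer reflectivities and attenuations, RPE baseline thickness
10 µm, choroid series between baseline and the trend, particle counts,
background level) values were chosen once to be typical of mouse retinal
OCT and are fixed; they are stated-world parameters, not tuning knobs.

Per-eye structure: a latent severity z ~ N(0,1) per eye raises day ≥ 1
ONL scattering (elevation 1.2 + 0.15 z) and shifts the day-20 ONL loss by
6 z µm plus independent 6 µm noise — equal signal and noise SDs make the
truth-level R² between day-1 ONL eAC and final loss 0.5 by construction
(the published point estimate). Small multiplicative per-eye thickness
jitter (SD 2%) is applied to the other layers. The mechanism linking
early reflectance to final loss is unknown in vivo; this shared-cause
construction is phenomenological.

**Not modelled:** eye motion, blinking, A-scan dropout, retinal
curvature arc-length effects, confocal/PSF axial sensitivity, multiple
scattering, particle shadowing, 3-D structure. A green test therefore
establishes that the estimators and pipeline are correct *for this image
formation model*, not that they are robust to every artifact of real
acquisitions; conversely the recovery tolerances (±1.5 µm thickness,
boundary MAE ≤ 1 px at default noise) are meaningful because the
generator's noise level is calibrated to 40-frame averaging.

## 8. Numerical and degenerate-input choices

- DP ties toward the smaller row; boundary ordering enforced by banding,
  with a 0.1 px minimum gap after sub-pixel refinement.
- Sub-pixel refinement offsets are clamped to ±0.5 px; non-concave
  stencils fall back to the integer row.
- `compute_eac` masks all-zero A-scans and tails below the floor;
  `layer_eac` returns NA with a zero count for empty ROIs rather than
  erroring.
- Scale invariance of eAC holds to machine precision (floating-point
  summation order), asserted at 1e-12.
- PGM image I/O quantizes to 16 bits with the scale recorded in the JSON
  sidecar; reading without the sidecar is an error (geometry is never
  defaulted). Plain-text PGM replaces TIFF/PNG because no image codec
  package is available in the target environment; contracts are
  unchanged.
- Seeds: every stochastic routine takes or derives an explicit seed;
  study runs derive per-image seeds from the master seed, so the same
  configuration reproduces byte-identical study tables.

## 9. Known limitations

- The choroid/sclera boundary has the weakest contrast; its error budget
  is double that of other boundaries (≤ 2 px MAE), matching its larger
  measurement variance in practice.
- The degenerative-schema OR band hides IS/OS substructure, so the Dip
  ratio is undefined from day 6 on (by design).
- eAC layer means carry the truncation and discretization biases
  described in §4; they are comparable across conditions but are not
  absolute scattering coefficients.
- The severity link and several optical parameters are phenomenological;
  recovering the designed R² validates the estimator chain, not the
  biology.
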