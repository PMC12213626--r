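# retoct

Quantitative analysis of retinal OCT B-scans for chemically induced
degeneration models in the mouse eye — and a ground-truthed synthetic
B-scan generator to validate every stage of the analysis.

## The problem

Sodium iodate (SI) kills the retinal pigment epithelium (RPE) and triggers
progressive photoreceptor degeneration. Longitudinal OCT imaging can track
this non-invasively, but quantifying it requires (i) segmenting retinal
layers in images that degrade as disease advances, (ii) measuring layer
thickness at standardized positions relative to the optic nerve head (ONH),
and (iii) turning raw intensities into attenuation-based reflectance
measures that are robust to anterior-segment optics. `retoct` implements
this pipeline for mice:

- **Segmentation** — exact dynamic-programming shortest paths over
  gradient cost maps extract 9 boundaries (normal retina: NFL, IPL, INL,
  OPL, ONL, IS+OS, RPE, choroid) or 8 boundaries once the IS+OS and RPE
  merge into a single outer-retina (OR) band in degenerated eyes. Several
  segmenter variants ("models") are combined by a per-A-scan median
  ensemble, with usage rates and Dice overlap for model comparison.
- **Morphometry** — two 200-A-scan ROIs per B-scan, 350–630 µm on either
  side of the detected ONH center; 4 B-scans × 2 ROIs = 8 ROI values are
  averaged per eye. Sub-pixel boundaries resolve effects well below the
  1.7 µm axial pixel (e.g. 0.5 µm RPE swelling).
- **Reflectance** — per-pixel estimated attenuation coefficients (eAC,
  m⁻¹), computed per A-scan as µ̂\[i\] = I\[i\] / (2·Δ·Σ_{j>i} I\[j\]) on the
  linear intensity scale after background subtraction (I(z) = U(z) − N).
  eAC is invariant to per-A-scan intensity scaling, which compensates
  vessel shadows and anterior-segment variation. Also the Dip ratio
  (IS-band peak / IS–OS hyporeflective minimum), an early degeneration
  biomarker.
- **Vitreous particles** — hyper-reflective blobs above the inner limiting
  membrane, counted by 8-connected component labeling with a 5–500 px area
  filter.
- **Time-course statistics** — exponential decay fits
  T(t) = C + A·e^(−kt) with half-decay ln 2 / k, OLS correlations with
  bootstrap R² confidence intervals, paired t-tests against baseline.
- **Phantom generator** — layered speckle phantoms (multiplicative
  Gamma(n, n) noise emulating n-frame averaging, two-way Beer–Lambert
  attenuation, ONH wedge, vitreous particles, sub-pixel boundaries) whose
  ground truth follows the published SI time course, including per-eye
  latent severity linking day-1 ONL reflectance elevation to final
  photoreceptor loss.

## Worked example

```r
library(retoct)

params  <- phantom_params()          # 1.7 um/px axial, 1000 A-scans/1.4 mm
model   <- degeneration_model()      # published SI time course
profile <- make_profile(params, model, day = 0)
rb  <- render_bscan(profile, params, seed = 42)

res <- analyze_bscan(rb$bscan, "normal")   # 5-variant ensemble + measures
subset(res$thickness, layer %in% c("ONL", "RPE", "choroid"))
#>         roi_side   layer    value
#> left.5      left     ONL 62.61475
#> left.7      left     RPE 10.08137
#> left.8      left choroid 88.50915
#> right.5    right     ONL 62.68576
#> right.7    right     RPE 10.02865
#> right.8    right choroid 88.66603

tab <- si_reference_thickness()
fit_exp_decay(tab$day, tab$ONL)
#> <exp_decay_fit> T(t) = 18.145 + 44.478 exp(-0.2270 t); half-decay 3.05 days (n=6)
```

The recovered ONL (62.6 µm vs. 62.62 µm generated), RPE (10.1 vs. 10.0)
and choroid (88.5/88.7 vs. 88.6) show the pipeline resolving layer
thickness to ~0.1 µm after ROI averaging, and the decay fit reproduces the
~3-day ONL half-reduction time characteristic of this SI dose.

A full simulated study (phantoms → segmentation → measurement → statistics):

```r
cfg <- run_config(design = list(n_mice = 7, eyes_per_mouse = 2,
                                bscans_per_eye = 4,
                                timepoints = c(0, 1, 3, 6, 13, 20)),
                  seed = 1)
res <- run_study(cfg)       # StudyTable + summary + decay fit + t-tests
res$summary                 # per-day mean +/- SD per layer
```

## Command line

```sh
Rscript inst/cli/retoct.R simulate --config cfg.json --out outdir --seed 1
Rscript inst/cli/retoct.R segment  --image scan.pgm --schema normal --out seg.csv
Rscript inst/cli/retoct.R run-all  --config cfg.json --out outdir
```

Images are plain-text 16-bit PGM with a JSON metadata sidecar (pixel
pitches, intensity scale); boundaries and study tables are CSV/JSON.

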