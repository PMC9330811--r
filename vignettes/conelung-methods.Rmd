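---
title: "Truncated-cone lung volumetry: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Truncated-cone lung volumetry: models, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Total lung volume is a routine readout in preclinical microCT studies of
lung disease, but the reference way of obtaining it — slice-wise manual
delineation of the lung with inter-slice interpolation — costs an
experienced operator 15–20 minutes per scan. Threshold segmentation of the
aerated parenchyma is fast but breaks down in pathology, because diseased
tissue densifies out of the aerated-lung radiodensity window and disappears
from the segmentation even though it still occupies thoracic space.

`conelung` implements a geometric shortcut. The thorax between the carina
and the diaphragmatic cupola is modelled as a conical frustum
parameterised by three landmark distances an operator can place in seconds:

* $d_s$ — the small-base span at the carina level, from one lung limit to
  the contralateral one (coronal view); when no lung is visible at that
  level, the rib-to-rib inner distance substitutes;
* $d_l$ — the large-base span at the diaphragm level, from the ventral
  aspect of the vertebrae to the abdominal wall (sagittal view);
* $h$ — the carina-to-diaphragm height.

With radii $R_1 = d_s/2$ and $R_2 = d_l/2$, the thoracic volume is the
standard conical-frustum volume

$$V_{thorax} = \frac{\pi h}{3}\left(R_1^2 + R_2^2 + R_1 R_2\right).$$

The measured spans cross the whole thorax, so the package halves them to
radii by default; because the halving convention is not independently
verifiable and any constant factor is absorbed by the regression step
below, the `halve_diameters` flag is exposed in `run_config()` for
sensitivity analysis.

The thoracic volume contains heart, vessels and chest-wall structures as
well as lung, but in a healthy animal the proportions of intrathoracic
structures are approximately constant. An ordinary-least-squares regression
of manually delineated lung volume on thoracic volume,

$$V_{lung}^{theo} = a \cdot V_{thorax} + b,$$

therefore converts the seconds-scale frustum measurement into a
*theoretical lung volume*, the end product of the protocol. The package
fits this with `fit_lung_regression()` (slope, intercept, $R^2$, Pearson
$r$, $p$-value, training range) and predicts with
`predict_theoretical_lung()`, which warns — rather than errors — outside
the training range, since pathologic thoraces legitimately exceed the
healthy calibration range.

## Supporting pipeline

**HU calibration** (`fit_hu_calibration()`, `apply_hu_calibration()`). Raw
grey values are mapped to Hounsfield units through the two-point scanner
calibration: the arithmetic mean grey inside an air VOI is anchored to
−1000 HU and a water VOI to 0 HU. The means are untrimmed, matching the
plain averaging of the bench protocol. Applying a calibration twice is
rejected.

**Threshold segmentation** (`threshold_segment()`). Aerated lung is
segmented by an inclusive HU window; two presets ship: the reference
(−700, −300) HU and the alternate (−700, −400) HU. The reference window
brackets the air/tissue mixture around its modal density of roughly
−500 HU while excluding pure air and soft tissue. Components touching the
volume border are removed (exterior air — a concern for phantoms, where the
animal does not fill the grid) together with components under 27 voxels
(noise specks; one 3×3×3 neighbourhood). Connected components are labelled
in 3-D by per-slice labelling merged across adjacent slices with
union-find. No smoothing or filtering is applied anywhere in the pipeline,
preserving original voxel intensities.

**Emulated manual delineation** (`delineate_from_contours()`). Slice-wise
closed polygons are rasterised by even-odd scan-line filling at voxel
centres; slices between two annotated ones are filled by linear
interpolation of the signed-distance transforms of the bounding
annotations, thresholded at zero. Signed-distance blending is a standard,
topology-tolerant emulation of the (undocumented) interpolation in the
interactive tools used at the bench; equivalence is claimed at the volume
level, not voxel-by-voxel. No mask is produced outside the annotated
extent.

**Validation battery** (`bland_altman()`, `gage_rr()`, `volume_ratios()`,
`classify_cohort()`).

* Bland–Altman agreement uses bias ± 1.96·SD (sample SD) limits; the fixed
  normal quantile is used rather than a small-sample $t$ correction, which
  matches the fixed 95% limits convention of the protocol.
* Gage R&R decomposes measurement variance by the two-way crossed ANOVA
  expected-mean-squares method into part, operator, operator×part
  interaction and repeatability; negative estimates are truncated to zero,
  and when the interaction mean square falls below error the interaction is
  pooled into error (the additive model is refitted), standard
  measurement-systems practice. The reported operator contribution is the
  operator-plus-interaction share of total variance.
* Classification applies a strict "deviation over 5%" rule against the mean
  lung volume of the control animals: a deviation of exactly 5% is
  negative. Sensitivity and specificity follow directly from the four
  branches (TP/FN for pathologic, FP/TN for controls).
* Because it is unstated whether cohort-level ratios are means of per-scan
  ratios or ratios of means — and printed cohort tables elsewhere match
  neither exactly — `summarise_ratios()` reports both.

## The synthetic thorax phantom

Every stage is testable without animal data through
`generate_thorax_phantom()`. Design choices:

* **Geometry.** The thoracic cavity is a solid of revolution with an
  elliptical cross-section interpolated from the carina plane to the
  diaphragm plane, plus a mild barrel bulge (8% sinusoidal excursion).
  This makes the frustum model a good but deliberately imperfect fit, so
  the regression stage has genuine residual error to absorb — a phantom
  that the frustum fitted exactly would make the calibration step
  untestable.
* **Intensities.** Background air −1000 HU; body soft tissue 40 HU; bone
  (ribs, vertebrae) 700 HU; lesions 30 HU; aerated parenchyma drawn from a
  Gaussian of mean −500 HU and SD 80 HU truncated to (−700, −300) HU,
  matching the reference window and modal lung density; optional additive
  Gaussian noise (default 25 HU, a mild reconstruction-noise floor).
* **Exact truths.** The cavity is split into lung and mediastinum, and the
  lung into aerated, non-aerated and lesion compartments, by ranking voxels
  on anatomical distance fields and cutting at exact voxel counts. Manifest
  volumes are therefore *identical* to voxel-count × voxel-volume of the
  generator masks, and the manifest carries exact landmark coordinates
  (both the lung-limit small base and the rib-to-rib fallback).
* **Grids.** The single-phantom default is 256³ voxels at 0.05 mm. Cohort
  simulations use 168 × 164 × 148 at 0.1 mm: cohort-level quantities are
  voxel-count-based truths and regression statistics, which are
  resolution-independent, and the coarser grid keeps a 40-phantom cohort
  near a minute. Unit tests use 96³ at 0.12 mm for the same reason.
* **Cohorts.** `generate_cohort()` draws a latent animal-size factor
  (U(0.875, 1.125)) scaling all three thorax dimensions together, with 4%
  independent shape jitter — cohort variation in animals is dominated by
  overall size, not shape. With the base geometry (8.75 / 11.25 / 11.75 mm)
  this yields healthy-cohort thoracic volumes of mean ≈ 890 mm³ and
  SD ≈ 190 mm³, the regime in which the protocol was characterised in
  vivo. Each phantom's lung fraction is then adjusted so that true lung
  volume follows $a V_{thorax} + b + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, with defaults $a = 0.20$,
  $b = 300$ mm³, $\sigma = 20$ mm³ — coefficients in the healthy
  lung-to-thorax ratio regime (lung fractions stay within 0.45–0.9 of the
  cavity for every drawable geometry). One master seed drives everything;
  per-phantom sub-seeds are derived deterministically, so cohorts are
  bit-reproducible.
* The calibration tube (`generate_calibration_phantom()`) is a
  two-compartment cylinder (water below, air above, thin denser wall) in
  raw grey values, with cylindrical VOIs strictly inside each compartment
  (> 10⁴ voxels each at the default grid, so a 50-grey noise SD leaves VOI
  means within fractions of a grey of the designed values).

**What the phantom does not model:** photon noise and beam hardening,
cardiac and respiratory motion (and respiratory phase generally), lobar
anatomy, and partial-volume mixing at tissue boundaries (compartments are
painted at their modal intensity). Tests passing on the phantom therefore
demonstrate correctness of the *computational protocol* — geometry,
calibration arithmetic, segmentation rules, statistics — not robustness to
scanner physics or motion artefacts.

## Numerical choices and degenerate inputs

* Physical coordinates are voxel-centre based: position = (index − 1) ×
  spacing, in mm; all distances in mm, volumes in mm³.
* Axis-aligned 90°/180° reorientations are detected (signed-permutation
  rotation matrices) and applied as exact voxel permutations; any other
  rigid rotation is resampled trilinearly about the volume centre on the
  unchanged grid (grey statistics are better conserved than with
  nearest-neighbour, and the protocol only needs small alignment
  corrections). Masks are resampled nearest-neighbour to stay binary.
  Rotation matrices must be orthonormal with positive determinant within
  1e−6.
* Window endpoints are inclusive; ties in the voxel-ranking splits of the
  phantom are broken by linear index, making the generator deterministic.
* The two-point HU calibration requires mean(water) > mean(air) and
  non-empty VOIs; the regression requires n ≥ 3 and non-degenerate
  predictor variance; Gage R&R requires a balanced crossed design with at
  least 2 parts, 2 operators, 2 replicates.
* Volumes are stored as double-precision NIfTI when in HU (so −1000
  survives a round trip bit-exactly) and integer otherwise; masks as
  8-bit.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script reproduce, from scratch: a
50-frustum comparison against an independent lattice-point-counting oracle
at 0.05 mm; exact and noisy (SD 50 grey) HU anchoring; aerated-volume
recovery on a zero-noise 256³ phantom; a 2 mm sphere delineated on every
2nd slice against its analytic 33.51 mm³; window-nesting on noisy and
pathologic phantoms; slope/intercept/R² recovery and mean theoretical-lung
deviation on a 40-phantom cohort; the Bland–Altman closed form on
d = {1, 2, 3} and a 10⁴-sample simulation; Gage R&R on a zero-operator-
variance design and a 200-replicate Monte Carlo against the analytic 3.81%
operator share; the four classification branches, the strict 5% boundary,
and a fully separable 7-pathologic/2-control cohort; and byte-identical
reports from two runs of the seeded end-to-end protocol.

## Known limitations

* The frustum mixes a left–right span at the carina with a dorso-ventral
  span at the diaphragm, exactly as the bench measurement does; it is a
  calibrated proxy, not a segmentation, and raw thoracic volumes depend on
  the halving convention (the regression absorbs the constant).
* Calibration is per-cohort ("specific correlation formulas for each
  model"): `run_protocol()` defaults to fitting on control scans and
  predicting for all; a fitted model should not be reused across scanner
  protocols or strains without refitting.
* Contour interpolation reproduces plausible interpolated masks, not any
  particular vendor implementation; agreement is asserted on volumes.
* Landmark placement itself is manual by design; automating
  carina/diaphragm detection is out of scope.
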