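---
title: "Moisture mapping in cooked meat by VIS/NIR hyperspectral imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moisture mapping in cooked meat by VIS/NIR hyperspectral imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hsimoist)
```

## The measurement and the model

A pushbroom VIS/NIR hyperspectral camera records, for every pixel of a
sample, a reflectance spectrum over 400–1,000 nm. Water absorbs in this
window through the O–H stretching overtones: a strong band near 970 nm and
a weak one near 760 nm. In cooked chicken breast, moisture spans roughly
63–73 % depending on cooking temperature, and the absorption depth at these
bands tracks it closely enough that a linear multivariate calibration
predicts moisture to a few tenths of a percentage point.

The pipeline has five stages, each a package function:

1. `calibrate_reflectance()` — raw counts to relative reflectance,
   `R = (R0 − D)/(W − D)` element-wise over the cube. The pixel index in
   this ratio is interpreted per pixel *and* per band (the only
   shape-consistent reading). Pixels with `W ≤ D` are set to `NA` and
   counted; clipping them would silently bias downstream spectra, and
   reflectance above 1 (specular highlights) is retained for the mask stage
   to deal with.
2. `band_difference()` + `auto_threshold()` + `threshold_mask()` —
   background separation. Tissue is bright in the red/NIR and the belt/board
   is dark everywhere, so the difference image (default 700 nm − 450 nm) is
   strongly bimodal; Otsu's criterion (exact maximization of between-class
   variance over all splits of the sorted values) picks the threshold.
   Foreground is strictly `> t`, ties to background, so masks are
   deterministic. No morphological clean-up is applied by default; an
   optional largest-connected-component filter exists
   (`largest_component()`).
3. `preprocess_fit()` / `preprocess_apply()` — the eight row-wise
   pre-treatments (raw, mean/max/range normalization, SNV, MSC,
   Savitzky–Golay 1st/2nd derivative). The fitted state is frozen and
   replayed on validation, test, and pixel spectra: in particular the MSC
   reference is the column-mean of the *calibration* spectra only, never of
   anything held out, so no information leaks through preprocessing.
4. `fit_plsr()` / `loo_cv()` / `evaluate_model()` / `select_model()` —
   NIPALS PLS1 and the reporting protocol.
5. `pls_image()` / `region_stats()` / `render_map()` — pixel-wise maps.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| wavelength grid | 400–1,000 nm, 5 nm (121 bands) | nm | spans the VIS/NIR window; the instrument's true band count is not fixed by the design, so a round 5 nm grid is used |
| NIR subset | 700–1,000 nm inclusive | nm | drops visible-range pigment information, keeping the O–H bands |
| segmentation band pair | 700 / 450 nm | nm | tissue bright at 700, dark at 450; background dark at both — configurable |
| SG window / degree | 11 points / 2 | bands | common chemometric default; derivatives are divided by (Δλ)^d so coefficients are per nm |
| SNV denominator | sample (n−1) sd | — | "unit variance" is ambiguous; fixed and documented |
| max latent variables | 20 | — | generous versus the ~2–7 the CV selects here |
| split | 52 calibration / 20 test, seeded uniform draw | — | the study's partition sizes; the draw mechanism is ours |
| column scaling | centered, not autoscaled | — | autoscaling would interact with SNV/MSC; `scale = TRUE` available |

Component count for the report tables is the lowest cross-validated RMSE
(ties toward fewer components). R² is always the coefficient of
determination 1 − SS\_res/SS\_tot, never squared Pearson correlation — the
two differ once predictions are biased, and only the former penalizes bias.

## The synthetic study

No scans are publicly deposited, so the generator is a first-class module
and defines the conditions every end-to-end test runs under:

* **Design.** 36 breasts, 12 per temperature (50/60/70 °C), two slices each
  (central/peripheral), 72 samples. True tissue moisture is uniform within
  70–73 / 66–70 / 63–66 % per temperature group.
* **Spectra.** A smooth logistic tissue baseline (dark blue end, bright
  red/NIR end) attenuated exponentially by Gaussian bands at 970 nm
  (strong) and 760 nm (weak): `R(λ) = B(λ)·exp(−(m/100)·A(λ))`. The
  exponential form matters: with purely linear depth on a fixed baseline,
  the per-spectrum standard deviation is itself proportional to moisture,
  and SNV's division by it removes the moisture signal at first order —
  making pixel-wise mapping after SNV impossible at any realistic noise
  level, which contradicts how these models behave on real tissue. Real
  diffuse reflectance saturates gently with absorber concentration; the
  exponential reproduces that, band depth stays monotone (near-linear over
  63–73 %) and vanishes at zero moisture.
* **Spatial structure.** Elliptical sample on a dark background; per-pixel
  moisture = sample moisture + a radial gradient (center wetter by 3
  points, rim drier) + 0.4-point pixel noise, recentered so the foreground
  mean equals the sample value exactly (the recovery tests rely on that
  identity).
* **Scatter.** Each *sample* gets a multiplicative gain (sd 0.05), additive
  offset (sd 0.02) and a wavelength tilt (sd 0.01); each *pixel*
  additionally gets its own gain (sd 0.03) and offset (sd 0.01). This is
  the variation SNV/MSC exist to remove — without it the preprocessing
  comparison would be vacuous. On top sits a white reflectance noise floor
  of 0.002 per pixel and band (residual shot/readout noise after the
  spectrograph's point-spread smoothing) and 2 counts of sensor noise on
  the raw scan.
* **Reference error.** The tabulated moisture is the tissue moisture plus a
  0.25-point weighing/drying error, and the three pan weights are
  synthesized to invert exactly to that measured value. Without this the
  response would be an exactly linear, error-free function of the spectra;
  cross-validation then keeps adding components with enormous coefficient
  norms, which is unfaithful to how calibrations behave on real reference
  chemistry (real SEC/SEV sit near a few tenths of a point, as they do
  here).
* **Acquisition.** One white/dark reference pair per session (shared across
  the 72 scans); raw counts are reflectance × (W − D) + D, so calibration
  exactly inverts the synthesis when noise is disabled.

What the generator does *not* emulate: specular highlights, instrument
smile/keystone, wavelength miscalibration, band-to-band correlated noise,
fat/protein compositional variation, or cooking kinetics. Passing the
recovery tests therefore shows the pipeline's algebra and plumbing are
right and that it behaves sensibly in a realistic noise regime — it does
not certify performance on any particular instrument.

## Map-aware component selection

The component count that minimizes sample-level CV error is not the right
count for pixel-wise mapping. Mean sample spectra average ~2,000 pixels and
are nearly noise-free, so cross-validation happily keeps components whose
regression vector has a very large norm; a pixel spectrum, by contrast,
carries white noise that propagates into the map as σ·‖β‖ (in the
preprocessed spectral space). `run_pipeline()` therefore selects the
mapping model's component count `a` to minimize

```
sqrt( RMSE_cv(a)^2 + (σ_px · ‖β_a‖)^2 )
```

where σ_px is estimated from preprocessed foreground pixel spectra by a
robust second-difference estimator (second differences of a smooth spectrum
are noise-dominated; medians resist curvature at the absorption bands).
This is fully data-driven — no ground truth, no tuned thresholds — and
typically lands on 2–3 components where the report tables choose 4–7. The
report tables themselves always use the lowest-RMSE rule.

The mapping model's pre-treatment defaults to SNV: per-spectrum scatter
correction is the standard choice for pixel-wise application because pixel
spectra carry strong scatter that sample means do not, and SNV (unlike MSC
with its stored reference, or the norm-based scalings) is exactly invariant
to per-pixel affine distortion. The mapping wavelength range defaults to
the full 400–1,000 nm model: more bands average the white noise further
down. Both are configurable (`map_method`, `map_range`).

## Numerical conventions and degenerate inputs

* Coordinates are `[row, col, band]`, wavelengths ascending; ENVI I/O
  supports BSQ/BIL/BIP, float32/float64/uint16, little/big endian.
* Savitzky–Golay edges are handled by evaluating the terminal-window
  polynomial fit at the edge offsets, so output length equals input length
  and polynomials of degree ≤ the filter order are reproduced exactly,
  edges included.
* NIPALS deflates X only (PLS1); component extraction stops early if the
  residual covariance `X'y` underflows (1e−12 relative), and later
  requested components then repeat the converged regression vector —
  numerically this is the OLS solution on the extracted subspace.
* Constant spectra are hard errors in SNV and the normalizations (the row
  transform is undefined); MSC warns and flags rows with non-positive
  fitted slope rather than failing the batch.
* In `select_model()` a failing pre-treatment yields an NA report row and a
  warning; the other methods complete.
* Chemical-image background is `NA` internally and −9999 in ENVI exports —
  never 0, which is a legal moisture percentage. Rendering clips to the
  display range (default 60–75 %) rather than rescaling, so maps of
  different samples are comparable.
* Center/periphery regions split the foreground at the median of the
  Euclidean distance transform (inner ≈50 % of the area is "center").

## Problem sizes

Default cubes are 64×64×121 (≈0.5 M values per sample, 72 samples), chosen
as desk-scale while leaving ~900 pixels per region for the
center/periphery statistics. The full pipeline — generation, calibration,
masking, 8 pre-treatments × 52-fold leave-one-out CV × 2 wavelength
ranges, and 72 maps — runs in well under a minute on one core.

## Known limitations

* PLS1 only (scalar response); no PLS2, PCR, or variable selection.
* The seven pre-treatments are fixed; no detrending/OSC/wavelets.
* The threshold/band-pair defaults suit dark-background scenes; scenes with
  bright sample holders need the parameters changed.
* Synthetic realism limits listed above; in particular the generator's
  moisture gradient magnitude (3 points center-to-rim) is a free parameter,
  not a measured value.
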