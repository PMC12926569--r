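---
title: "Methods: spectral photoacoustic collagen quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral photoacoustic collagen quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacollagen)
```

## The mixing model and its assumptions

A photoacoustic image records, per pixel, acoustic pressure proportional to
absorbed optical energy. Under three assumptions — a constant Grüneisen
parameter, spatially uniform fluence within a frame, and per-pixel signal
that is the sum of contributions from collagen, oxyhemoglobin and
deoxyhemoglobin only — the fluence-normalized intensity at wavelength
$\lambda_w$ is linear in the chromophore concentrations:

$$\frac{I(\lambda_w, p)}{\Phi(\lambda_w)} \;=\; \sum_{c}
\tilde\varepsilon_c(\lambda_w)\, x_c(p),$$

where $\tilde\varepsilon_c$ is the *min-max-normalized* absorption spectrum
of chromophore $c$ and $x_c(p) \ge 0$ the relative concentration at pixel
$p$. Hemoglobin absorbs orders of magnitude more strongly than collagen;
normalizing each spectrum to $[0,1]$ over the NIR-I window equalizes the
chromophores' leverage in the least-squares system, at the cost of making
the recovered $x_c$ *relative* rather than molar quantities. All outputs
are therefore in arbitrary units, rescaled so that 1000 a.u. corresponds to
relative concentration 1 (the rescale makes the small collagen fractions
legible next to hemoglobin).

The Grüneisen parameter is fixed at 1 and absorbed into the arbitrary
units. The sum-to-one constraint is applied per pixel — the only reading
consistent with producing per-pixel concentration maps.

## Reference spectra

The package ships tabulated spectra for collagen, Hb and HbO₂ on a 2 nm
grid over 640–1010 nm (`inst/extdata/spectra/`). These files are
**synthetic reconstructions**, marked as such in their filenames and
`# source:` headers: the hemoglobin tables are spline interpolations
through anchor values transcribed from the standard compiled
oxy/deoxyhemoglobin extinction tabulation, and the collagen curve is
shaped to the published NIR-I feature set — global maximum at 690 nm, local
minimum near 850 nm, local maximum near 910 nm, local minimum near 940 nm —
that motivated the five imaging wavelengths {690, 750, 850, 910, 940} nm.
Because min-max normalization removes absolute scale, only spectral
*shape* enters the unmixing; `mass_to_molar_absorptivity()` is provided for
completeness (dividing an absorption coefficient by the pure substance's
molar concentration, `mass_density / molar_mass`) and is shape-neutral by
construction.

Two numerical choices here:

* **Normalization window** — 650–1000 nm (the NIR-I window), the range over
  which the features above are defined. The window is recorded on the
  normalized object.
* **Interpolation** — piecewise linear between tabulated points when
  sampling spectra at imaging wavelengths. The grid is dense (2 nm), so
  interpolation error is negligible against every tolerance used here.

`build_design_matrix()` refuses rank-deficient systems (naming the
collinear columns) and reports the condition number — about 21 for the
packaged spectra at the default wavelengths. The chromophore column order
(collagen, HbO₂, Hb) is fixed globally to prevent silent label swaps.

## Fluence normalization

Pulse energy varies with wavelength, so each per-wavelength image is
divided by the mean fluence of that wavelength: per-pulse fluence is
measured energy over the beam's focal-spot area (0.51 cm², the default in
`acquisition_config()`), averaged over all pulses of the scan. This is a
*scan-average* normalization — one divisor per wavelength, not per frame.
A per-frame variant is deliberately out of scope: because the unmixing
output is scale-invariant per pixel (the sum constraint removes overall
scale), only *relative* errors between wavelengths matter, and the
scan-average is the quantity the energy log estimates well.

## The constrained solver

The published procedure states two output constraints: concentrations sum
to 1, and negative values are replaced by 0. Clipping *after* renormalizing
would break the sum, so the implemented order is: ordinary least squares
(closed form on the 5×3 system, shared across all pixels of a stack), clip
negatives to 0, then rescale to sum 1. Both stated constraints hold at the
output. Pixels whose solution clips to the zero vector (no signal, or all
negative coefficients) are flagged *degenerate* and returned as zeros
rather than NaN, so downstream means stay well defined; degenerate pixels
are excluded from ROI means because their zeros are imputed, not measured.

An exact non-negative least-squares mode (`solver = "nnls"`, active-set
enumeration over the 7 possible supports — exact for 3 chromophores) is
available for sensitivity analysis; it is not the default because the
published description is post-hoc clipping. No spatial regularization is
applied: unmixing is strictly per pixel.

The test suite checks the solver against a brute-force oracle: a grid
search over the concentration simplex (coarse sweep, staged local
refinement to $10^{-3}$ resolution) minimizing the scale-free residual.
On interior pixels the clip step is inert and the solver must match the
oracle at grid resolution; everywhere, the NNLS mode's residual must not
exceed the grid minimizer's.

## Regions of interest

ROIs are simple polygons drawn per frame, stored in JSON sidecars whose
header declares the coordinate convention (0-based pixel centers, x =
column, y = row, origin top-left). Rasterization uses the even-odd rule on
pixel centers and is checked against an independent point-in-polygon
implementation. Organ summaries are **pixel-pooled**: the mean is taken
over the union of all ROI pixels across the organ's frames, not a mean of
per-frame means; the pooled mean equals the pixel-count-weighted mean of
per-frame means (tested as an exact identity).

## Histology calibration

Trichrome sections are separated into stain densities by the
optical-density method: $OD = -\log_{10}(I/I_0)$ per RGB channel
($I_0 = 255$ for 8-bit images), densities are the OD vector through the
inverse stain basis, clipped at 0. The default basis is the published
Masson-trichrome pair used by the standard Fiji plugin (blue collagen
stain, red cytoplasm stain), completed with the unit-normalized cross
product. Note the completed third direction has a negative component —
only the two physical stains generate valid images, which the round-trip
tests respect.

Tissue is masked by total OD exceeding 0.05 (white background has zero
OD). The collagen area fraction is the fraction of tissue pixels whose
blue density exceeds a threshold: Otsu's method on the in-mask blue
densities by default (deterministic, parameter-free), or a fixed numeric
threshold. Otsu assumes both stained and unstained pixels are present; on
single-class sections (area fraction 0 or 1, as the synthetic recovery
ladder includes by construction) its between-class criterion is
undefined, so the ladder validation uses the fixed mode at half the
generator's blue density. Section exclusions (tears, folds, missing os
sections) are a data-curation decision, not an image-analysis one: keep an
exclusion column in your measurement table and filter before calibration.

Calibration itself is ordinary least squares of sPA organ means on area
fractions over matched (animal, organ) pairs, with $R^2$ and the two-sided
slope p-value (t, $n-2$ df), refusing fewer than 3 pairs or zero predictor
variance.

## Cohort statistics

* **t-tests** — Student's pooled-variance unpaired test by default ("the"
  unpaired t-test); Welch by flag. Group orientation is deterministic
  (factor levels, else sorted labels), so normal-vs-prolapsed signs are
  stable.
* **Two-way ANOVA** — Type II sums of squares by default, recorded in the
  output. The motivating design is balanced (4 animals per group in the
  age-matched slice), where Types I/II/III coincide (tested); Type III is
  computed under sum-to-zero contrasts, without which it is not meaningful.
* **Age regressions** — per organ and per group (the study's figures show
  split lines); pooling is available by flag. The age-matched slice for
  group comparisons is 4–8 months inclusive.
* **Age ANOVAs** — the source analyses report two-way ANOVAs "of age with
  prolapse" and "of age with anatomical position" without stating whether
  age was a continuous covariate or a binned factor. Both are exposed;
  the default treats age as a continuous covariate (ANCOVA-style), the
  less lossy choice, with a median-split binned mode for comparison.
* **Multiple testing** — raw per-organ p-values by default, matching the
  source's reporting; a Holm flag exists.

All statistics delegate to base R and `car` (t.test, lm, anova,
`car::Anova`); the tests validate them against closed-form hand formulas
and a 2000-replicate null simulation of the two-way ANOVA's type-I error.

## What the synthetic generators emulate — and what they do not

`generate_phantom()` draws from the forward model exactly: region-wise
constant concentrations, per-wavelength fluences, additive Gaussian noise
truncated at zero (the sources state no noise model; zero-truncated
Gaussian is the standard desk-scale stand-in), and an energy log with ±5%
multiplicative per-pulse jitter recentred so scan means equal the true
fluences. The default layout is four rectangular "organs" with collagen
fractions 0.10/0.20/0.30/0.30 and blood at 40% sO₂ — a documented fixture,
not a claim about tissue. Not modeled: acoustic propagation and the probe
point-spread function, speckle, depth-dependent fluence, motion. Passing
the phantom suite therefore demonstrates correctness of the *algebra and
bookkeeping* of the pipeline on model-consistent data, not robustness to
the physics the forward model omits.

`generate_cohort()` defaults emulate the motivating study's design: two
groups of eight animals aged 2–12 months, four organs each, collagen
rising with age in the normal group and falling in the prolapsed group
(steepest in the external os: +40 vs −30 a.u./month), between-animal s.d.
40 a.u. shared across an animal's organs, residual s.d. 60 a.u. For the
organs reported as not differing between groups, the two groups' trend
lines cross at 6 months — the centre of the age-matched window — so only
the external os carries a group deficit there. Responses are floored at 0
to respect the concentration scale.

`generate_histology()` places exactly `round(blue_fraction × n_tissue)`
blue pixels at random in an elliptical tissue footprint and renders
through Beer–Lambert with 8-bit quantization. It does not emulate fiber
texture, stain gradients, or scanner illumination fields.

## Numerical and I/O choices

* Stack TIFFs are written as 32-bit pages with intensities rescaled into
  $[0,1]$ by a power-of-two factor recorded in the JSON sidecar; the
  round trip is exact to about $2^{-32}$ of full scale (the available TIFF
  writer stores 32-bit integer samples). Metadata carries wavelengths,
  acquisition constants, the normalization flag and the coordinate
  convention.
* Double fluence-normalization, un-normalized stacks fed to the unmixer,
  empty ROIs, degenerate spectra, rank-deficient designs, saturated or
  empty-celled ANOVA designs, and undersized regressions all raise typed
  errors (classed conditions) rather than returning silent defaults.
* Otsu thresholding uses a 256-bin histogram; thresholds are recorded in
  the measurement output.

Validation problem sizes are chosen to exercise every code path while
keeping the default suite fast: end-to-end identity on a 10-frame 128×128
phantom, 1000-pixel oracle comparison, 10,000-pixel noise study,
2000-replicate ANOVA null simulation, and 200-replicate power and
Monte-Carlo checks.

## Known limitations

* **Per-pixel accuracy at realistic noise.** The normalized collagen and
  Hb spectra are similar over the five wavelengths (design-matrix
  condition number ≈ 21), so noise is amplified along the collagen–Hb
  ambiguity. At 20 dB SNR the validation suite measures a per-pixel
  collagen-fraction mean absolute error of ≈ 0.18 for the default solver
  (≈ 0.16 for the NNLS mode) — far above what the conditioning would
  permit for a well-separated basis. Reliable quantification at this SNR
  comes from ROI averaging over thousands of pixels, not from single
  pixels; the noiseless end-to-end identity and the organ-mean recovery
  tests are the meaningful accuracy statements.
* The packaged spectra are reconstructions (above); absolute molar
  absorptivities are not reproduced, only shapes.
* The real study's regression/ANOVA statistics are not reproducible —
  no animal data are deposited; the cohort generator reproduces the
  *structure* of those analyses, not their numbers.
* Elastin (spectrally similar to collagen) and collagen subtypes are not
  unmixed; NIR-II approaches (collagen/water ratios) are out of scope.
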