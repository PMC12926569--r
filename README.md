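# spacollagen

Spectral photoacoustic (sPA) quantification of relative collagen content in
soft tissue, with histology calibration and cohort statistics.

## The problem

Collagen remodeling in the female reproductive tract is implicated in
disorders such as pelvic organ prolapse, but quantifying soft-tissue
collagen today requires a biopsy. Ultrasound-guided spectral photoacoustic
imaging offers a non-invasive alternative: photoacoustic images acquired at
several NIR-I wavelengths can be decomposed, pixel by pixel, into the
contributions of the dominant absorbers — collagen, oxyhemoglobin (HbO₂)
and deoxyhemoglobin (Hb).

This package implements that analysis as a tested, reusable pipeline for
multiwavelength photoacoustic image stacks, aimed at imaging scientists who
want to reproduce or extend per-organ collagen estimation in small-animal
reproductive-tract studies (a Fibulin-5 knockout prolapse model, in the
motivating application).

## The model

With constant Grüneisen parameter and per-wavelength fluence Φ(λ), the
fluence-normalized photoacoustic intensity of a pixel is modeled as a
linear mixture

I(λ) / Φ(λ) = Σ_c ε̃_c(λ) · x_c,

where ε̃_c is the min-max-normalized absorption spectrum of chromophore
c ∈ {collagen, HbO₂, Hb} (normalization equalizes the weight of weak and
strong absorbers) and x_c is the relative concentration. Five wavelengths
{690, 750, 850, 910, 940} nm, chosen around features of the collagen
spectrum, over-determine the three unknowns. Per pixel the pipeline:

1. solves the 5×3 linear least-squares system `A x ≈ I`,
2. replaces negative concentrations with 0,
3. rescales so the chromophore sum equals 1, and
4. maps relative concentration to arbitrary units (1000 a.u. = 1).

Fluence is estimated per pulse as energy / beam area (0.51 cm²) and
averaged per wavelength over the scan. Organ-level estimates are means of
the collagen channel over polygonal regions of interest drawn per frame.
Calibration regresses sPA organ means on the collagen area fraction of
Masson's-trichrome-stained sections (Ruifrok–Johnston color
deconvolution). Cohort statistics are unpaired t-tests, two-way ANOVAs and
per-group age regressions. An sO₂ map (HbO₂/(HbO₂+Hb)) comes for free.

Every input has a seeded synthetic generator with known ground truth
(tissue phantoms from the forward model, trichrome-like sections, energy
logs, ROI annotations, cohorts), so the whole pipeline is testable end to
end.

## Worked example

```r
library(spacollagen)

design <- load_reference_spectra() |> minmax_normalize() |> build_design_matrix()
design
#> <spa_design_matrix> 5 wavelengths x 3 chromophores, condition number 20.98
#>     collagen     HbO2      Hb
#> 690  1.00000 0.001256 0.47659
#> 750  0.53030 0.250669 0.27757
#> 850  0.00000 0.807210 0.05761
#> 910  0.27273 0.976234 0.06999
#> 940  0.07576 0.967989 0.05823

spec <- phantom_spec(image_size = c(64, 64), n_frames = 3,
                     noise_sigma = 0.02, seed = 42)
phantom <- generate_phantom(spec, design)
fluences <- mean_fluence(phantom$pulses, phantom$stack$config)
conc <- phantom$stack |> fluence_normalize(fluences) |> unmix_stack(design)
organ_mean(conc, phantom$annotations, animal_id = "SYN01")
#> # A tibble: 4 × 5
#>   animal_id organ       mean_collagen_au n_pixels n_frames
#> 1 SYN01     uterus                  100.     1974        3
#> 2 SYN01     internal_os             200.     1974        3
#> 3 SYN01     external_os             300.     1974        3
#> 4 SYN01     vagina                  300.     1974        3
```

The phantom's four regions were generated with true collagen fractions
0.10 / 0.20 / 0.30 / 0.30, so the recovered organ means (in a.u., where
1000 a.u. = relative concentration 1) sit on the ground truth despite the
added noise. The phantom's blood compartment is at 40% oxygen saturation
and the sO₂ map recovers it: `mean(so2_map(conc), na.rm = TRUE)` prints
`0.4065182`.

Cohort statistics on a synthetic cohort with a prescribed external-os
deficit in the prolapsed group:

```r
cohort <- generate_cohort(cohort_spec(seed = 1))$cohort
results <- run_study_tables(cohort)
results$ttests[, c("organ", "t_statistic", "df", "p_value")]
#>   organ       t_statistic    df p_value
#> 1 uterus            0.479     5 0.652
#> 2 internal_os      -0.124     5 0.906
#> 3 external_os       6.43      5 0.00135
#> 4 vagina           -0.407     5 0.701
```

Only the external cervical os — the organ the generator endowed with a
group deficit — is significant, and the per-group age regressions recover
the prescribed opposite-signed slopes (+40 vs −30 a.u./month configured;
+41.1 and −31.2 fitted).

`plot_spectra()`, `autoplot()` on concentration maps and calibration fits,
and `plot_cohort()` provide ggplot2 graphics; `tidy()`/`glance()` methods
give broom-style tables.

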