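# sifdown

Canopy-to-leaf downscaling of far-red solar-induced chlorophyll
fluorescence (SIF), with a fully synthetic, ground-truthed test bed.

## The problem

Far-red SIF retrieved at 760 nm from airborne imaging spectroscopy is a
*canopy-level, directional* signal (SIF₇₆₀ᶜᵃⁿᵒᵖʸ, mW m⁻² nm⁻¹ sr⁻¹). Leaves,
however, emit a *hemispherical* flux, and part of it is scattered and
re-absorbed on its way out of the canopy. The escape fraction
f_esc (0 ≤ f_esc ≤ 1) links the two scales, and without correcting for it —
and for the incoming light — diurnal SIF maps confound plant physiology with
canopy structure.

`sifdown` implements the full downscaling chain for crops with contrasting
canopy architecture (a rosette crop whose leaf angles change over the day, a
homogeneous cereal, a row-planted orchard):

1. **SFM retrieval** — SIF₇₆₀ and reflectance are decoupled from at-sensor
   radiance around the O₂-A absorption band by spectral fitting
   (polynomial reflectance × atmospheric transmittance + Gaussian-shaped
   fluorescence), after calibrating an *effective surface–sensor distance*
   so that non-vegetated pixels (NDVI ≤ 0.1) retrieve zero SIF.
2. **fAPAR estimation** —
   WDRVI = (αR_NIR − R_red)/(αR_NIR + R_red) with α = 0.1,
   fAPAR_green = 0.516·WDRVI + 0.726, fAPAR_chl = k·fAPAR_green with
   k = 0.79, APAR_chl = fAPAR_chl · PAR.
3. **Downscaling** — FCVI = R(770) − mean R(400–700) ≈ fAPAR_chl · f_esc, so
   f_esc = FCVI / fAPAR_chl (masked where FCVI < 0.18 or f_esc > 1), and
   SIF₇₆₀ˡᵉᵃᶠ = π · SIF₇₆₀ᶜᵃⁿᵒᵖʸ / f_esc (mW m⁻² nm⁻¹).
4. **Emission efficiency** — ε_SIF(PAR) = SIF₇₆₀ˡᵉᵃᶠ / PAR and
   ε_SIF(FCVI) = π · SIF₇₆₀ᶜᵃⁿᵒᵖʸ / (FCVI · PAR), the latter algebraically
   cancelling fAPAR_chl.
5. **Diurnal analysis** — per-field percentile boxes, canopy-vs-leaf pixel
   correlations, and efficiency-vs-light hysteresis loops across a six-
   overpass diurnal sequence (10:10 … 17:15, solar noon 13:30).

Because no public airborne dataset accompanies this problem, the package
ships a first-class **synthetic scene generator**: diurnal clear-sky PAR,
per-pixel truth (fAPAR, f_esc with crop-specific diurnal dynamics, an
NPQ-like afternoon depression of emission efficiency), top-of-canopy
reflectance that encodes the truth exactly, and at-sensor radiance with a
parametric O₂-A band, path radiance, 0.28 nm FWHM instrument convolution and
seeded noise. Every stage of the pipeline is therefore testable against
known truth.

## Worked example

```r
library(sifdown)

run <- run_pipeline(run_config(nx = 48L, ny = 48L, seed = 1L, snr = 250))
run
#> <sif_run> 48 x 48 pixels, 6 overpasses, 6 fields; d* = 1.000, 1.000, 1.000, 1.000, 1.000, 1.000

glance(run$retrievals[[4]])          # overpass 4 (14:40)
#>   d_star mean_ref_sif n_ref poor_calibration n_converged n_failed median_rms
#> 1  1.000    -2.27e-10   953 FALSE                   2304        0      0.278
```

The calibrated distance scale d\* equals the simulated truth (1.0) and the
mean reference-pixel SIF is numerically zero: the zero-SIF calibration
objective is met. Escape-fraction field statistics show the structural
contrast between the crops — constant in time for the cereal, rising from
morning to mid-afternoon for the rosette crop:

```r
dplyr::filter(run$field_summaries, variable == "fesc", overpass %in% c(1, 4))
#>    field           crop time   p25   p50   p75   n
#>     SU-1 sugarbeet_like 10.2 0.610 0.622 0.635 247
#>     WH-1     wheat_like 10.2 0.545 0.549 0.553 225
#>     OR-1   orchard_like 10.2 0.480 0.527 0.613 168
#>     SU-1 sugarbeet_like 14.7 0.680 0.692 0.705 247
#>     WH-1     wheat_like 14.7 0.545 0.549 0.553 225
#>     OR-1   orchard_like 14.7 0.527 0.575 0.658 185
```

Canopy and leaf SIF maps are near-perfectly correlated for the homogeneous
cereal and much less so for the structurally heterogeneous orchard:

```r
dplyr::filter(run$crop_correlations, overpass == 4)
#>             crop overpass time r_mean     r_sd n_fields
#> 1 sugarbeet_like        4 14.7  0.953 0.000728        2
#> 2     wheat_like        4 14.7  0.991 0.000672        2
#> 3   orchard_like        4 14.7  0.750 0.025311        2
```

And the emission efficiency versus PAR traces an open hysteresis loop —
afternoon branch below the morning branch at matched light levels
(3.16e-05 nm⁻¹ at 11:15 vs 2.79e-05 nm⁻¹ at 15:50 for the cereal):

```r
dplyr::filter(run$hysteresis_par, crop == "wheat_like")
#>         crop time driver_mean eps_mean   eps_sd   n
#> 1 wheat_like 10.2      297759 3.17e-05 2.42e-06 447
#> 2 wheat_like 11.2      345958 3.16e-05 2.48e-06 447
#> 3 wheat_like 12.5      380305 3.08e-05 2.35e-06 447
#> 4 wheat_like 14.7      377186 2.88e-05 2.18e-06 447
#> 5 wheat_like 15.8      342812 2.79e-05 2.11e-06 447
#> 6 wheat_like 17.2      275479 2.64e-05 2.05e-06 447

plot_hysteresis(run$hysteresis_par)  # ggplot of the loops
```

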