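---
title: "Methods: forward model, SIF retrieval and canopy-to-leaf downscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward model, SIF retrieval and canopy-to-leaf downscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sifdown` downscales far-red solar-induced chlorophyll fluorescence (SIF)
retrieved at 760 nm from canopy to leaf level and normalizes it into an
emission efficiency, across a diurnal sequence of overpasses. This vignette
documents the science the package implements, the choices made where the
method leaves room, and what the synthetic test bed does and does not show.

## The downscaling chain

The directional canopy signal and the hemispherical leaf emission are linked
by the escape fraction:

$$\mathrm{SIF}_{760}^{leaf} \;=\; \frac{\pi\,\mathrm{SIF}_{760}^{canopy}}{f_{esc}},
\qquad 0 \le f_{esc} \le 1 .$$

$f_{esc}$ is estimated from top-of-canopy reflectance through the
fluorescence correction vegetation index,
$\mathrm{FCVI} = R_{770} - \overline{R_{400-700}}$, which approximates
$f_{APAR} \cdot f_{esc}$ for dense canopies, so that
$f_{esc} \approx \mathrm{FCVI}/f_{APAR,chl}$. $f_{APAR,chl}$ comes from the
wide dynamic range vegetation index,
$\mathrm{WDRVI} = (\alpha R_{NIR} - R_{red})/(\alpha R_{NIR} + R_{red})$
with $\alpha = 0.1$ on the 795–810 nm and 665–680 nm band means, mapped
linearly as $f_{APAR,green} = 0.516\,\mathrm{WDRVI} + 0.726$ and scaled by
$k = 0.79$ (valid for leaf chlorophyll above ~20 µg cm⁻²). Two efficiency
normalizations remove the effect of incident light: per unit PAR, and per
unit PAR absorbed by chlorophyll. The latter admits the cancellation

$$\varepsilon_{SIF}^{APAR_{chl}}
 = \frac{\mathrm{SIF}_{760}^{leaf}}{f_{APAR,chl}\cdot \mathrm{PAR}}
 \;\equiv\;
 \frac{\pi\,\mathrm{SIF}_{760}^{canopy}}{\mathrm{FCVI}\cdot \mathrm{PAR}}
 = \varepsilon_{SIF}^{FCVI},$$

which the package asserts pixelwise on every run (to 1e-12 relative): it is
an algebraic identity once $f_{esc}$ comes from the FCVI ratio, and any
violation indicates an implementation defect.

Key thresholds: pixels with FCVI < 0.18 are excluded (soil-contaminated,
the index is not meaningful over sparse canopies); computed $f_{esc} > 1$ is
physically impossible and is masked with a dedicated flag rather than
clipped, so such pixels remain auditable. Each invalid pixel carries exactly
one reason code, assigned in the order `missing`, `low_fcvi`,
`nonpos_fapar`, `fesc_gt_1`.

## SFM retrieval

At-sensor radiance around the O₂-A band is modelled as

$$L(\lambda) = \frac{E_g T_\downarrow T_\uparrow}{\pi} R(\lambda)
 + A\, g(\lambda)\, T_\uparrow + L_{path}(\lambda),$$

with $R(\lambda)$ a quadratic polynomial over the fit window and
$g(\lambda)$ a fixed Gaussian fluorescence shape (peak 740 nm, σ = 25 nm)
normalized to 1 at 760 nm, so the free amplitude $A$ *is* SIF₇₆₀. The model
is linear in its free parameters; the "fit" is therefore solved exactly —
no iterative optimizer, no convergence tuning. Three steps compose the
scene retrieval:

1. **Reference pixels.** All pixels with NDVI ≤ 0.1 (threshold inclusive)
   from the companion reflectance cube; an empty set is an error because
   the calibration is then impossible. Without a reflectance cube a
   radiance-ratio proxy over the edges of the radiance cube's own range is
   used — a documented dialect difference.
2. **Effective distance.** The O₂ absorption depth scales with a
   dimensionless surface–sensor distance $d$ via Beer–Lambert extinction.
   The calibration scans a grid in $d$ (default 0.6–1.4, step 0.05),
   retrieving SIF for up to 2000 seeded reference pixels at each point, and
   picks the $d$ whose *mean reference SIF is zero* — soil does not
   fluoresce. Because the signed mean crosses zero almost linearly while
   its absolute value is V-shaped, the refinement between grid points is a
   root search on the signed mean (tolerance 1e-7); a parabolic step on the
   absolute value is the fallback when the scan shows no sign change. The
   retrieved SIF is steeply sensitive to $d$, so polishing the root far
   below the grid step is what makes noise-free recovery exact for
   distances off the grid.
3. **Per-pixel fit.** Weighted linear least squares. The noise model is
   multiplicative (per-band SD = signal/SNR), so in-trough bands — where
   the radiance and hence the noise are small but the fluorescence
   in-filling is most informative — carry the largest weights. Weights come
   from a first-pass unweighted fit's fitted values rather than the raw
   spectrum, which removes the weight–noise correlation bias that raw
   weights introduce. Small negative amplitudes down to −1 mW m⁻² nm⁻¹ sr⁻¹
   are admitted to avoid truncation bias; amplitudes below that floor, and
   pixels whose design is rank-deficient, are flagged `failed` with missing
   outputs, never silently zero. A spectrum without an absorption band in
   the window makes the SIF column nearly polynomial; the fit refuses to
   report an amplitude when the orthogonal fraction of the (weighted) SIF
   column falls below 5 %.

**Fit window.** The default is 750–778 nm. The absorption system of the
parametric atmosphere spans roughly 759–772 nm; including the band's red
wing and continuum on both sides lowers the amplitude noise floor enough to
meet the 1 % round-trip requirement at SNR 500, which the narrower
20 nm window just misses. The window, polynomial degree (2) and SIF shape
are all configurable through `retrieval_config()`.

## The synthetic scene generator

The generator is the package's study design: it produces the conditions the
analysis assumes, with known per-pixel truth.

* **Illumination.** Clear-sky PAR from the cosine of the solar zenith angle
  (latitude 50.6°, day of year 180, solar noon 13:30), scaled so zenith sun
  gives 438 W m⁻² (2000 µmol m⁻² s⁻¹ via the 0.219 conversion). Six default
  overpasses: 10:10, 11:15, 12:30, 14:40, 15:50, 17:15 local time.
* **Crops.** Three archetypes on a six-field rectangular layout inside a
  soil margin. Per-pixel fAPAR_chl and base f_esc are drawn around the
  archetype means; biochemical heterogeneity (fAPAR, emission efficiency)
  and structural heterogeneity (f_esc) are parameterized separately because
  they are distinct properties of real canopies: a cereal stand has nearly
  uniform structure even where chlorophyll varies, which is exactly why its
  canopy and leaf SIF maps correlate almost perfectly, whereas a mixed-age
  orchard is dominated by structural variability. Defaults:
  fAPAR_chl 0.72/0.55/0.45, f_esc 0.62/0.55/0.50, biochemical
  heterogeneity 0.08/0.06/0.20 and structural 0.03/0.01/0.20 for the
  sugarbeet-, wheat- and orchard-like archetypes. These place midday
  canopy SIF near 3 and leaf SIF near 17 mW m⁻² nm⁻¹ (sr⁻¹) for the
  rosette crop — the plausible ranges for mid-summer European crops.
* **Diurnal f_esc.** Three shapes: a smooth monotone ramp from the first
  morning overpass to ~14:40 followed by a plateau (rosette crops move from
  erectophile to planophile leaf orientation as the day warms), a constant
  (spherical, constant leaf angle distribution), and a solar-noon-centred
  Gaussian bump for the orchard — around noon only the sunlit crown tops
  contribute and scattering is weakest, so f_esc peaks; the method itself
  pins down only the first two shapes and the midday bump is this package's
  modelling choice for row-tree canopies.
* **Efficiency and hysteresis.** The emission efficiency follows
  $\varepsilon(t) = \varepsilon_{max}\,(1 - d_{npq} H(t))\,
  \frac{PAR}{PAR + K}$ with $\varepsilon_{max} = 10^{-4}\,nm^{-1}$,
  $K = 1.5\times10^{5}$ mW m⁻², depression depth $d_{npq} = 0.3$ and $H(t)$
  the normalized PAR history low-pass filtered with a 2.5 h time constant —
  the simplest mechanism that delays recovery after the midday light peak
  and so puts the afternoon branch of the ε–PAR relation below the morning
  branch. Setting $d_{npq} = 0$ closes the loop exactly, which the tests
  exploit.
* **Reflectance.** In `consistent` mode the spectrum is flat in the
  visible, rises through a smoothstep red edge confined to 700–750 nm, and
  is constant on the NIR plateau; visible level and plateau are solved so
  that the FCVI and WDRVI identities hold *exactly* (relative error below
  1e-10 in the tests). Pixels whose fAPAR_green admits no valid solution
  are flagged and given the flat soil spectrum rather than a distorted one.
  `toy_rt` mode instead mixes fixed vegetation and soil endmembers by
  canopy cover, so recovery is only approximate (median f_esc error within
  15 % for dense canopies) — the robustness counterpart to the exact mode.
* **Radiance.** The forward operator evaluates the linear surface–
  atmosphere model on a 0.1 nm grid, convolves with a Gaussian 0.28 nm FWHM
  instrument response, resamples to 0.11 nm sensor bands over 670–780 nm
  (the sampling interval is a configurable default; only the FWHM is
  pinned), and adds seeded Gaussian noise with per-band SD = signal/SNR.
  The atmosphere is parametric: a fixed sum-of-Gaussians O₂ absorption
  profile (band-core upward transmittance ≈ 0.09 at d = 1), downward
  optical depth 0.55 of the upward one, a small smooth path-radiance
  continuum, spherical-albedo coupling set to zero.

What the generator does **not** emulate: real radiative-transfer fidelity
(no SCOPE/PROSAIL/MODTRAN coupling), bidirectional reflectance and SIF
anisotropy, flight-line mosaicking artefacts, clouds or illumination
variability, the O₂-B band, and any coupling between reflectance noise and
radiance noise (the TOC reflectance is emitted noise-free; noise enters the
radiance only). Passing tests therefore demonstrate the *internal
consistency and statistical behaviour* of the chain under the stated
assumptions, not its accuracy on real imagery.

## Numerical and design choices

* Band windows are half-open $[lo, hi)$ on band centres; the FCVI NIR term
  is the band nearest 770 nm within ±5 nm (no interpolation).
* fAPAR_green is clamped to [0, 1] with a clamp count attached as an
  attribute — the linear mapping exceeds 1 for WDRVI > ~0.531, which dense
  canopies legitimately reach; erroring would reject valid pixels.
* Percentiles use linear interpolation between order statistics
  (`quantile(type = 7)`); zonal membership uses pixel-centre-in-polygon
  with an even-odd ray cast, centres on edges excluded.
* Crop-level correlation aggregation is the unweighted mean ± SD of
  field-level Pearson r.
* PAR is a scene scalar per overpass (single weather station), not a grid.
* All randomness flows from one seed via fixed per-stage substreams
  (truth: seed; radiance noise: seed + 1000 + overpass), so stages are
  independently reproducible and a rerun is bit-identical.
* Interchange formats are plain text: cubes as a header + band-sequential
  ASCII dialect (wavelength list mandatory), grids and tables as CSV, field
  layouts as GeoJSON, configuration as YAML with unknown keys rejected,
  manifests as JSON with a configuration hash.

## Problem sizes

The shipped tests run the exact identities and structural checks on 24–48
pixel scenes, the toy-mode robustness bound at 100 × 100, and the
parameter-recovery checks on a 128 × 128 scene (noise-free retrieval and
distance calibration on a single overpass; the full six-overpass pipeline
at SNR 250). These sizes were chosen as the smallest at which field-level
statistics are stable; the generator itself is O(pixels × bands) and scales
to larger scenes linearly.

## Known limitations

The FCVI-based escape fraction is unreliable for sparse canopies (hence the
0.18 exclusion) and for geometrically complex row canopies, where the
downscaled maps should be read qualitatively; kernel-driven BRDF methods
would be the next step there. The WDRVI→fAPAR mapping carries its
calibration's assumptions (no leaf clumping, chlorophyll above
20 µg cm⁻²); in `toy_rt` mode this is the dominant recovery error. The
parametric atmosphere preserves the band-depth/distance structure the
retrieval exploits but nothing else about real atmospheres — in particular
the spherical-albedo coupling is absent, so the retrieval's accuracy
against this generator is an upper bound on what matched real atmospheric
tables could deliver.
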