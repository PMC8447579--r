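#' Parametric O2-A band atmosphere
#'
#' A desk-scale stand-in for a radiative-transfer-derived atmospheric
#' characterization: transmittances follow Beer-Lambert extinction through a
#' fixed synthetic O2 absorption profile (a sum of Gaussians spanning
#' 759-770 nm, band-core optical depth ~2.4 so that the upward transmittance
#' at the reference distance scale d = 1 drops to ~0.09), path radiance is a
#' small smooth continuum, the ground solar irradiance is a smooth continuum
#' scaled per overpass, and spherical-albedo coupling is set to zero. The
#' band depth deepens monotonically with the dimensionless surface-sensor
#' distance scale `d`, which is the structure the effective-distance
#' calibration of the retrieval exploits.
#'
#' @param wl_range Fine-grid wavelength range (nm), default c(668, 782).
#' @param wl_step Fine-grid step (nm), <= 0.1 recommended.
#' @param distances Distance-scale grid used by the retrieval calibration.
#' @param down_factor Ratio of downward to upward optical depth (the solar
#'   path traverses part of the absorbing column), default 0.55.
#' @param e760 Ground solar irradiance continuum at 760 nm for the reference
#'   illumination (mW m-2 nm-1), default 1050.
#' @param e_ref_ppfd PPFD of the reference illumination (umol m-2 s-1);
#'   per-overpass irradiance scales as `ppfd / e_ref_ppfd`.
#' @return An object of class `atmospheric_table` with the fine wavelength
#'   grid, the absorption profile `k_o2`, `e_ground`, path-radiance
#'   parameters and the distance grid.
#' @export
atmospheric_table <- function(wl_range = c(668, 782), wl_step = 0.1,
                              distances = seq(0.6, 1.4, by = 0.05),
                              down_factor = 0.55,
                              e760 = 1050, e_ref_ppfd = 2000) {
  stopifnot(wl_step > 0, wl_step <= 0.1 + 1e-12, all(distances > 0))
  wl <- seq(wl_range[1], wl_range[2], by = wl_step)
  k_o2 <- 2.4 * exp(-(wl - 760.6)^2 / (2 * 0.7^2)) +
    1.8 * exp(-(wl - 763.8)^2 / (2 * 1.2^2)) +
    1.0 * exp(-(wl - 766.8)^2 / (2 * 1.6^2))
  e_ground <- e760 * (760 / wl)^2
  structure(
    list(wavelength = wl, k_o2 = k_o2, distances = sort(distances),
         down_factor = down_factor, e_ground = e_ground,
         e_ref_ppfd = e_ref_ppfd),
    class = "atmospheric_table"
  )
}

#' @export
print.atmospheric_table <- function(x, ...) {
  cat(sprintf(
    "<atmospheric_table> %.1f-%.1f nm @ %.3g nm, d grid [%.2f, %.2f] (%d), band-core T_up(d=1) = %.3f\n",
    min(x$wavelength), max(x$wavelength),
    x$wavelength[2] - x$wavelength[1],
    min(x$distances), max(x$distances), length(x$distances),
    min(atm_t_up(x, 1))
  ))
  invisible(x)
}

#' Atmospheric terms at a distance scale
#'
#' Upward / downward transmittance and path radiance on the fine wavelength
#' grid of an [atmospheric_table()], evaluated at distance scale `d`
#' (continuous; `d` need not lie on the calibration grid).
#'
#' @param atm An `atmospheric_table`.
#' @param d Dimensionless distance scale (> 0).
#' @return Numeric vector on `atm$wavelength`.
#' @export
atm_t_up <- function(atm, d) exp(-atm$k_o2 * d)

#' @rdname atm_t_up
#' @export
atm_t_down <- function(atm, d) exp(-atm$k_o2 * d * atm$down_factor)

#' @rdname atm_t_up
#' @export
atm_l_path <- function(atm, d) {
  (0.15 + 0.10 * d) * (760 / atm$wavelength)^4
}

#' Fixed SIF emission spectrum shape
#'
#' Single-Gaussian far-red SIF spectral shape, normalized to 1 at 760 nm so
#' that its amplitude parameter is directly SIF at 760 nm.
#'
#' @param peak_wavelength Peak position (nm), default 740.
#' @param peak_width_sigma Gaussian sigma (nm), default 25.
#' @return A function `g(wavelength)` with attributes recording the
#'   parameters.
#' @export
sif_spectrum <- function(peak_wavelength = 740, peak_width_sigma = 25) {
  stopifnot(peak_width_sigma > 0)
  g <- function(wavelength) {
    exp(-((wavelength - peak_wavelength)^2 - (760 - peak_wavelength)^2) /
          (2 * peak_width_sigma^2))
  }
  attr(g, "peak_wavelength") <- peak_wavelength
  attr(g, "peak_width_sigma") <- peak_width_sigma
  g
}
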