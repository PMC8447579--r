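gaussian_srf_matrix <- function(band_centres, fine_wl, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- outer(band_centres, fine_wl, function(b, l) exp(-(l - b)^2 / (2 * sigma^2)))
  sweep(w, 1, rowSums(w), "/")
}

interp_to_fine <- function(values, coarse_wl, fine_wl) {
  if (min(fine_wl) < min(coarse_wl) || max(fine_wl) > max(coarse_wl)) {
    stop("fine wavelength grid extends beyond the reflectance cube range")
  }
  j <- findInterval(fine_wl, coarse_wl, rightmost.closed = TRUE)
  frac <- (fine_wl - coarse_wl[j]) / (coarse_wl[j + 1] - coarse_wl[j])
  frac[is.na(frac)] <- 0 # fine point exactly on last coarse band
  jhi <- pmin(j + 1, length(coarse_wl))
  n <- nrow(values)
  values[, j, drop = FALSE] * rep(1 - frac, each = n) +
    values[, jhi, drop = FALSE] * rep(frac, each = n)
}

#' Simulate at-sensor radiance around the O2-A band
#'
#' Combined surface-atmosphere forward model on the fine wavelength grid of
#' the atmospheric table:
#' `L = E_g T_down R T_up / pi + SIF T_up + L_path`,
#' where the SIF spectrum is the fixed shape scaled per pixel so that its
#' value at 760 nm equals the truth canopy SIF. The fine-grid radiance is
#' convolved with a Gaussian instrument response (default FWHM 0.28 nm),
#' resampled to the sensor band grid (670-780 nm, default 0.11 nm spacing),
#' and optionally degraded with Gaussian noise of per-band standard
#' deviation `signal / snr` (seeded; `snr = Inf` is noise-free).
#'
#' @param reflectance Top-of-canopy reflectance [spectral_cube()] covering
#'   the fine grid range.
#' @param truth Matching overpass of a [generate_truth()] tibble (supplies
#'   per-pixel canopy SIF).
#' @param atm An [atmospheric_table()].
#' @param distance True distance scale of the scene (default 1).
#' @param ppfd Overpass PPFD (umol m-2 s-1); sets the irradiance scale
#'   relative to `atm$e_ref_ppfd`.
#' @param sif_shape SIF spectral shape from [sif_spectrum()].
#' @param fwhm Instrument FWHM (nm), default 0.28.
#' @param band_step Sensor band spacing (nm), default 0.11.
#' @param band_range Sensor band range (nm), default c(670, 780).
#' @param snr Per-band signal-to-noise ratio, default `Inf`.
#' @param seed Integer seed for the noise stream.
#' @param chunk Pixels per processing block (memory control).
#' @return A radiance [spectral_cube()] (mW m-2 nm-1 sr-1).
#' @export
to_at_sensor <- function(reflectance, truth, atm, distance = 1,
                         ppfd = atm$e_ref_ppfd,
                         sif_shape = sif_spectrum(),
                         fwhm = 0.28, band_step = 0.11,
                         band_range = c(670, 780),
                         snr = Inf, seed = 1, chunk = 4096) {
  stopifnot(inherits(reflectance, "spectral_cube"),
            inherits(atm, "atmospheric_table"), fwhm > 0, distance > 0)
  truth <- dplyr::arrange(truth, .data$pixel)
  if (nrow(truth) != nrow(reflectance$values)) {
    stop("truth and reflectance cube disagree on pixel count")
  }
  sif <- truth$sif_canopy
  if (sif_shape(760) <= 0 && any(sif > 0)) {
    stop("SIF shape is non-positive at 760 nm but the truth emission is not zero")
  }

  wl <- atm$wavelength
  t_up <- atm_t_up(atm, distance)
  t_dn <- atm_t_down(atm, distance)
  l_path <- atm_l_path(atm, distance)
  e_scale <- ppfd / atm$e_ref_ppfd
  refl_gain <- atm$e_ground * e_scale * t_dn * t_up / pi
  sif_basis <- sif_shape(wl) * t_up

  bands <- seq(band_range[1], band_range[2], by = band_step)
  srf <- gaussian_srf_matrix(bands, wl, fwhm)
  tw <- t(srf)

  n <- nrow(truth)
  out <- matrix(NA_real_, n, length(bands))
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    r_fine <- interp_to_fine(reflectance$values[lo:hi, , drop = FALSE],
                             reflectance$wavelength, wl)
    l_fine <- r_fine * rep(refl_gain, each = hi - lo + 1) +
      outer(sif[lo:hi], sif_basis) +
      rep(l_path, each = hi - lo + 1)
    out[lo:hi, ] <- l_fine %*% tw
  }
  if (is.finite(snr)) {
    if (snr <= 0) stop("`snr` must be positive")
    set.seed(seed)
    out <- out + stats::rnorm(length(out), sd = abs(out) / snr)
  }
  spectral_cube(out, bands, nx = reflectance$nx, ny = reflectance$ny,
                units = "mW m-2 nm-1 sr-1", kind = "radiance",
                time = truth$time[1])
}
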