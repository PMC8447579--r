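#' Vegetation indices on reflectance values
#'
#' `wdrvi()` is the wide dynamic range vegetation index
#' `(alpha * nir - red) / (alpha * nir + red)` with weighting factor
#' `alpha = 0.1` by default; it reduces to the NDVI at `alpha = 1`.
#' `ndvi()` is provided on the same band windows for the retrieval's
#' reference-pixel selection. Pixels with both inputs zero are missing;
#' negative reflectance is an error.
#'
#' @param nir,red Band-mean reflectances (e.g. over 795-810 nm and
#'   665-680 nm).
#' @param alpha WDRVI weighting factor, default 0.1.
#' @return Numeric vector in \[-1, 1\].
#' @examples
#' wdrvi(0.5, 0.05)      # 0
#' wdrvi(0.2, 0.2)       # (0.1 - 1) / (0.1 + 1)
#' @export
wdrvi <- function(nir, red, alpha = 0.1) {
  if (any(nir < 0 | red < 0, na.rm = TRUE)) {
    stop("reflectance must be non-negative")
  }
  num <- alpha * nir - red
  den <- alpha * nir + red
  ifelse(den == 0, NA_real_, num / den)
}

#' @rdname wdrvi
#' @export
ndvi <- function(nir, red) wdrvi(nir, red, alpha = 1)

#' fAPAR of green canopy material from WDRVI
#'
#' Linear mapping `fAPAR_green = 0.516 WDRVI + 0.726`, calibrated on canopy
#' radiative-transfer simulations over a broad range of canopy and
#' illumination conditions. Output is clamped to \[0, 1\] (the linear form
#' exceeds 1 for WDRVI > ~0.531, which dense canopies legitimately reach);
#' the number of clamped pixels is attached as attribute `"n_clamped"`.
#'
#' @param wdrvi WDRVI values in \[-1, 1\].
#' @return fAPAR_green in \[0, 1\], with attribute `n_clamped`.
#' @examples
#' fapar_green(0)   # 0.726
#' fapar_green(-1)  # 0.21
#' @export
fapar_green <- function(wdrvi) {
  if (any(abs(wdrvi) > 1 + 1e-9, na.rm = TRUE)) {
    stop("`wdrvi` must lie in [-1, 1]")
  }
  raw <- 0.516 * wdrvi + 0.726
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "n_clamped") <- sum(raw != out, na.rm = TRUE)
  out
}

#' fAPAR of leaf chlorophyll
#'
#' `fAPAR_chl = k * fAPAR_green`, with `k` the ratio of chlorophyll to
#' green-material absorption. The default `k = 0.79` represents canopies
#' with leaf chlorophyll content above 20 ug cm-2.
#'
#' @param fapar_green fAPAR_green values in \[0, 1\].
#' @param k Scalar in (0, 1\].
#' @return fAPAR_chl values.
#' @examples
#' fapar_chl(1)  # 0.79
#' @export
fapar_chl <- function(fapar_green, k = 0.79) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0 || k > 1) {
    stop("`k` must be a scalar in (0, 1]")
  }
  k * fapar_green
}

#' PAR absorbed by chlorophyll
#'
#' `APAR_chl = fAPAR_chl * PAR`, with PAR the scene-scalar weather-station
#' measurement for the overpass in mW m-2.
#'
#' @param fapar_chl fAPAR_chl values.
#' @param par_mw PAR in mW m-2 (scalar, >= 0).
#' @return APAR_chl in mW m-2.
#' @export
apar_chl <- function(fapar_chl, par_mw) {
  if (any(par_mw < 0, na.rm = TRUE)) stop("`par_mw` must be non-negative")
  fapar_chl * par_mw
}

#' Per-pixel vegetation index and fAPAR maps from a reflectance cube
#'
#' Computes the red and NIR band means (665-680 and 795-810 nm, half-open
#' windows on band centres), the NDVI and WDRVI, and the fAPAR_green /
#' fAPAR_chl maps, as one tidy table.
#'
#' @param reflectance Reflectance [spectral_cube()].
#' @param alpha WDRVI weighting factor, default 0.1.
#' @param k fAPAR_chl / fAPAR_green ratio, default 0.79.
#' @param par_mw Optional overpass PAR (mW m-2); when supplied an
#'   `apar_chl` column is added.
#' @return A tibble with columns `pixel`, `x`, `y`, `nir`, `red`, `ndvi`,
#'   `wdrvi`, `fapar_green`, `fapar_chl` (and `apar_chl`).
#' @export
vegetation_indices <- function(reflectance, alpha = 0.1, k = 0.79,
                               par_mw = NULL) {
  nir <- band_mean(reflectance, c(795, 810))
  red <- band_mean(reflectance, c(665, 680))
  w <- wdrvi(nir, red, alpha)
  fg <- fapar_green(w)
  out <- cube_pixels(reflectance) |>
    dplyr::mutate(nir = nir, red = red,
                  ndvi = ndvi(nir, red), wdrvi = w,
                  fapar_green = as.numeric(fg),
                  fapar_chl = fapar_chl(.data$fapar_green, k))
  if (!is.null(par_mw)) {
    out <- dplyr::mutate(out, apar_chl = apar_chl(.data$fapar_chl, par_mw))
  }
  out
}
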