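#' Default reflectance band grid
#'
#' Band centres of the simulated broadband (DUAL-like) reflectance cube:
#' 400-900 nm at 3.65 nm spacing.
#'
#' @return Numeric vector of wavelengths (nm).
#' @export
default_reflectance_wavelength <- function() seq(400, 900, by = 3.65)

# red-edge transition: exactly 0 for wl <= 700, exactly 1 for wl >= 750,
# C1-smooth cubic in between. Keeping the fit window (>= 750 nm) on the NIR
# plateau makes the reflectance there exactly constant.
red_edge <- function(wl, lo = 700, hi = 750) {
  u <- pmin(pmax((wl - lo) / (hi - lo), 0), 1)
  u^2 * (3 - 2 * u)
}

#' Top-of-canopy reflectance consistent with scene truth
#'
#' Builds a smooth per-pixel reflectance spectrum (flat visible segment,
#' logistic-like red edge, NIR plateau) whose band statistics encode the
#' truth exactly, so the downstream index pipeline inverts it:
#'
#' * the reflectance at 770 nm minus the mean visible (400-700 nm)
#'   reflectance equals `fapar_chl * fesc` (the FCVI identity),
#' * the red (665-680 nm) and NIR (795-810 nm) band means yield a WDRVI
#'   whose linear fAPAR mapping returns `fapar_green` exactly.
#'
#' Writing `w` for the WDRVI implied by `fapar_green` (clipped to
#' \[-1, 1\]) and `c = alpha (1 - w) / (1 + w)`, the NIR plateau is
#' `p = fapar_chl * fesc / (1 - c)` and the visible level is `c * p`.
#' Pixels whose `fapar_green` leaves no solution with `0 <= c * p < p <= 1`
#' (`c >= 1`) are
#' flagged, not silently altered. Bare-soil pixels get a flat spectrum
#' (`soil_albedo`), hence zero FCVI and zero NDVI.
#'
#' `mode = "toy_rt"` instead mixes fixed vegetation and soil endmember
#' spectra by canopy cover, so the pipeline recovers the truth only
#' approximately; it exists for robustness tests.
#'
#' @param truth One overpass of a [generate_truth()] tibble.
#' @param wavelength Band centres (nm), default
#'   [default_reflectance_wavelength()].
#' @param mode `"consistent"` (exact inverse construction) or `"toy_rt"`.
#' @param alpha WDRVI weighting factor (default 0.1).
#' @param soil_albedo Flat soil reflectance (default 0.18).
#' @return A reflectance [spectral_cube()]. The integer vector of flagged
#'   (non-invertible) pixels is attached as attribute `"flagged"`.
#' @export
truth_to_reflectance <- function(truth,
                                 wavelength = default_reflectance_wavelength(),
                                 mode = c("consistent", "toy_rt"),
                                 alpha = 0.1, soil_albedo = 0.18) {
  mode <- match.arg(mode)
  stopifnot(length(unique(truth$overpass)) == 1)
  truth <- dplyr::arrange(truth, .data$pixel)
  nx <- max(truth$x) + 0.5; ny <- max(truth$y) + 0.5
  n <- nrow(truth)
  edge <- red_edge(wavelength)

  if (mode == "consistent") {
    w <- pmin(pmax((truth$fapar_green - 0.726) / 0.516, -1), 1)
    cc <- alpha * (1 - w) / (1 + w)
    f <- truth$fapar_chl * truth$fesc
    p <- f / (1 - cc)
    r <- cc * p
    bad <- !truth$soil & (!is.finite(p) | cc >= 1 | p > 1 | r < 0)
    p[truth$soil | bad] <- soil_albedo
    r[truth$soil | bad] <- soil_albedo
    # R(wl) = r + (p - r) * edge(wl): VIS exactly r, NIR plateau exactly p
    values <- outer(r, 1 - edge) + outer(p, edge)
    flagged <- which(bad)
  } else {
    # independent two-endmember mixture: vegetation spectrum scaled by an
    # interception proxy, plus exposed soil
    i0 <- pmin(truth$fapar_green / 0.95, 1)
    veg_vis <- 0.025 + 0.06 * (1 - truth$fapar_green)
    veg_nir <- ifelse(truth$soil, 0, truth$fesc) * truth$fapar_chl /
      pmax(i0, 1e-6) + veg_vis
    veg <- outer(veg_vis, 1 - edge) + outer(veg_nir, edge)
    soil_spec <- soil_albedo * (0.85 + 0.3 * (wavelength - 400) / 500)
    values <- veg * i0 + outer(1 - i0, soil_spec)
    values[truth$soil, ] <- rep(soil_spec, each = sum(truth$soil))
    flagged <- integer(0)
  }

  cube <- spectral_cube(values, wavelength, nx = round(nx), ny = round(ny),
                        units = "1", kind = "reflectance",
                        time = truth$time[1])
  attr(cube, "flagged") <- flagged
  cube
}
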