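#' Fluorescence correction vegetation index
#'
#' `FCVI = R_NIR - mean(R_VIS)`: the reflectance nearest 770 nm (within
#' `nir_tol` nm) minus the unweighted mean reflectance over the visible
#' window (400-700 nm, half-open on band centres). FCVI approximates
#' `fAPAR x f_esc` for far-red SIF.
#'
#' @param reflectance Reflectance [spectral_cube()].
#' @param nir_wavelength NIR reference wavelength (nm), default 770.
#' @param nir_tol Maximum distance to the nearest band centre (nm),
#'   default 5.
#' @param vis_window Visible window (nm), default c(400, 700).
#' @return Numeric vector, one FCVI value per pixel.
#' @export
fcvi <- function(reflectance, nir_wavelength = 770, nir_tol = 5,
                 vis_window = c(400, 700)) {
  band_at(reflectance, nir_wavelength, tol = nir_tol) -
    band_mean(reflectance, vis_window)
}

#' Escape fraction of far-red SIF
#'
#' `f_esc = FCVI / fAPAR_chl`, valid only where FCVI is at least `fcvi_min`
#' (observations below 0.18 are excluded as soil-contaminated) and
#' fAPAR_chl is positive. Pixels whose computed ratio exceeds 1 are
#' physically impossible and are masked with flag `fesc_gt_1` rather than
#' clipped, so they stay auditable. Each invalid pixel carries exactly one
#' reason code, assigned in the order `missing` (either input missing),
#' `low_fcvi`, `nonpos_fapar`, `fesc_gt_1`.
#'
#' @param fcvi FCVI values.
#' @param fapar_chl fAPAR_chl values, aligned with `fcvi`.
#' @param fcvi_min Inclusive FCVI validity threshold, default 0.18.
#' @return A tibble with columns `fesc` (`NA` where invalid), `valid`, and
#'   `flag` (`"ok"` or a reason code).
#' @examples
#' escape_fraction(0.45, 0.75)  # fesc = 0.6
#' @export
escape_fraction <- function(fcvi, fapar_chl, fcvi_min = 0.18) {
  if (length(fcvi) != length(fapar_chl)) {
    stop("`fcvi` and `fapar_chl` grids are not aligned")
  }
  fesc_raw <- ifelse(fapar_chl > 0, fcvi / fapar_chl, NA_real_)
  flag <- dplyr::case_when(
    is.na(fcvi) | is.na(fapar_chl) ~ "missing",
    fcvi < fcvi_min ~ "low_fcvi",
    fapar_chl <= 0 ~ "nonpos_fapar",
    fesc_raw > 1 ~ "fesc_gt_1",
    .default = "ok"
  )
  valid <- flag == "ok"
  tibble::tibble(
    fesc = ifelse(valid, fesc_raw, NA_real_),
    valid = valid,
    flag = flag
  )
}

#' Leaf-level SIF760
#'
#' Hemispherical leaf-level SIF emission
#' `SIF760_leaf = pi * SIF760_canopy / f_esc` (mW m-2 nm-1; the factor pi
#' converts the directional canopy radiance, per steradian, to the
#' hemispherical leaf emission). Computed on valid pixels only; missing
#' elsewhere.
#'
#' @param sif_canopy Canopy SIF760 (mW m-2 nm-1 sr-1).
#' @param fesc Escape fraction, > 0 on valid pixels.
#' @param valid Logical validity mask.
#' @return Leaf SIF760 (mW m-2 nm-1), `NA` on invalid pixels.
#' @export
sif_leaf <- function(sif_canopy, fesc, valid = !is.na(fesc)) {
  bad <- valid & (is.na(fesc) | fesc <= 0)
  if (any(bad)) {
    stop("escape fraction must be positive on valid pixels ",
         "(mask contract violated for ", sum(bad), " pixels)")
  }
  ifelse(valid, pi * sif_canopy / fesc, NA_real_)
}

#' Downscale canopy SIF to leaf level over a pixel table
#'
#' Data-frame-first wrapper chaining [escape_fraction()] and [sif_leaf()]:
#' takes a table with `fcvi`, `fapar_chl` and `sif_canopy` columns and
#' appends `fesc`, `valid`, `flag` and `sif_leaf`.
#'
#' @param data A data frame with columns `fcvi`, `fapar_chl`, `sif_canopy`.
#' @param fcvi_min Inclusive FCVI validity threshold, default 0.18.
#' @return `data` with downscaling columns appended.
#' @export
downscale_sif <- function(data, fcvi_min = 0.18) {
  ef <- escape_fraction(data$fcvi, data$fapar_chl, fcvi_min)
  data |>
    dplyr::mutate(
      fesc = ef$fesc, valid = ef$valid, flag = ef$flag,
      sif_leaf = sif_leaf(.data$sif_canopy, ef$fesc, ef$valid)
    )
}
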