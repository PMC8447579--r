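#' PAR unit conversions
#'
#' Photosynthetic photon flux density (PPFD, umol m-2 s-1, 400-700 nm) is
#' converted to energy units with the approximate factor
#' 1 umol m-2 s-1 = 0.219 W m-2, and further to mW m-2 so that PAR is
#' commensurable with SIF radiance units.
#'
#' @param ppfd Photosynthetic photon flux density (umol m-2 s-1), >= 0.
#' @return `ppfd_to_w()`: PAR in W m-2; `ppfd_to_mw()`: PAR in mW m-2.
#' @examples
#' ppfd_to_w(1)     # 0.219
#' ppfd_to_mw(2000) # 438000
#' @export
ppfd_to_w <- function(ppfd) {
  if (any(ppfd < 0, na.rm = TRUE)) stop("`ppfd` must be non-negative")
  0.219 * ppfd
}

#' @rdname ppfd_to_w
#' @export
ppfd_to_mw <- function(ppfd) 1000 * ppfd_to_w(ppfd)

#' Solar geometry for a set of acquisition times
#'
#' Computes solar zenith and azimuth angles from day of year, latitude and
#' local solar time using the standard Cooper declination formula and the
#' hour angle relative to solar noon.
#'
#' @param time Local time in decimal hours.
#' @param doy Day of year (default 180, end of June).
#' @param latitude Site latitude in degrees (default 50.6).
#' @param solar_noon Local time of solar culmination in decimal hours
#'   (default 13.5, i.e. 13:30).
#' @return A tibble with columns `time`, `sza`, `saa`, `doy`, `latitude`.
#' @export
solar_geometry <- function(time, doy = 180, latitude = 50.6, solar_noon = 13.5) {
  if (length(time) == 0) stop("`time` must contain at least one record")
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  h <- 15 * (time - solar_noon)          # hour angle, deg
  to_rad <- pi / 180
  cos_sza <- sin(latitude * to_rad) * sin(decl * to_rad) +
    cos(latitude * to_rad) * cos(decl * to_rad) * cos(h * to_rad)
  sza <- acos(pmin(pmax(cos_sza, -1), 1)) / to_rad
  # azimuth measured clockwise from north; atan2 convention, afternoon > 180
  saa <- (180 + h) %% 360
  tibble::tibble(time = time, sza = sza, saa = saa,
                 doy = doy, latitude = latitude)
}

#' Clear-sky diurnal PAR course
#'
#' Generates the idealized clear-sky photosynthetically active radiation
#' course driving the scene simulator:
#' `ppfd(t) = (par_max / 0.219) * max(cos sza(t), 0)`, so that `par_max`
#' (W m-2) is the PAR reached at zenith sun. Each record carries PPFD
#' (umol m-2 s-1) together with its W m-2 and mW m-2 representations.
#'
#' @param geometry A solar-geometry tibble from [solar_geometry()].
#' @param par_max PAR at solar zenith angle zero, W m-2 (> 0).
#' @return A tibble with columns `time`, `sza`, `ppfd`, `par_w`, `par_mw`.
#' @examples
#' g <- solar_geometry(c(10.17, 13.5, 17.25))
#' diurnal_par(g, par_max = 438)
#' @export
diurnal_par <- function(geometry, par_max = 438) {
  if (!is.data.frame(geometry) || nrow(geometry) == 0) {
    stop("`geometry` must be a non-empty solar-geometry data frame")
  }
  if (!is.numeric(par_max) || par_max <= 0) stop("`par_max` must be > 0")
  geometry |>
    dplyr::mutate(
      ppfd = (par_max / 0.219) * pmax(cos(.data$sza * pi / 180), 0),
      par_w = ppfd_to_w(.data$ppfd),
      par_mw = ppfd_to_mw(.data$ppfd)
    ) |>
    dplyr::select(dplyr::all_of(c("time", "sza", "ppfd", "par_w", "par_mw")))
}

#' Default overpass times
#'
#' Six acquisition times (decimal hours, local time) spanning a diurnal
#' course three times before and three times after a 13:30 solar noon:
#' 10:10, 11:15, 12:30, 14:40, 15:50 and 17:15.
#'
#' @return Numeric vector of six times in decimal hours.
#' @export
default_overpass_times <- function() {
  c(10 + 10 / 60, 11 + 15 / 60, 12.5, 14 + 40 / 60, 15 + 50 / 60, 17.25)
}
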