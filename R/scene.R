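#' Simulate a diurnal multi-overpass scene
#'
#' End-to-end forward simulation with known ground truth: clear-sky diurnal
#' PAR, per-pixel canopy truth per overpass, top-of-canopy reflectance
#' consistent with that truth, and at-sensor radiance around the O2-A band.
#' All randomness derives from the single `seed` via fixed per-stage
#' substreams, so a fixed seed gives a bit-identical scene.
#'
#' @param nx,ny Scene dimensions in pixels (default 64 x 64).
#' @param archetypes Crop archetypes, default [default_archetypes()].
#' @param layout Field layout, default [default_field_layout()].
#' @param times Overpass times, default [default_overpass_times()].
#' @param par_max Clear-sky PAR at zenith sun (W m-2), default 438.
#' @param doy,latitude,solar_noon Solar geometry parameters.
#' @param distance True atmospheric distance scale, default 1.
#' @param snr Radiance signal-to-noise ratio, default `Inf`.
#' @param mode Reflectance construction mode, `"consistent"` or `"toy_rt"`.
#' @param atm Atmospheric table, default [atmospheric_table()].
#' @param sif_shape SIF spectral shape, default [sif_spectrum()].
#' @param seed Integer master seed.
#' @param k Ratio fAPAR_chl / fAPAR_green used by the truth generator.
#' @param ... Further arguments passed to [generate_truth()] (e.g. `d_npq`,
#'   `eps_max`, `npq_tau`, `light_half_sat`).
#' @return A `sif_scene` list with elements `truth` (long tibble),
#'   `par` (fine-grid PAR series), `overpasses` (per-overpass PAR records),
#'   `reflectance` and `radiance` (lists of [spectral_cube()]s, one per
#'   overpass), `atm`, `layout`, `archetypes` and `config`.
#' @export
simulate_scene <- function(nx = 64, ny = 64,
                           archetypes = default_archetypes(),
                           layout = default_field_layout(nx, ny),
                           times = default_overpass_times(),
                           par_max = 438, doy = 180, latitude = 50.6,
                           solar_noon = 13.5,
                           distance = 1, snr = Inf,
                           mode = c("consistent", "toy_rt"),
                           atm = atmospheric_table(),
                           sif_shape = sif_spectrum(),
                           seed = 1, k = 0.79, ...) {
  mode <- match.arg(mode)
  grid_times <- sort(unique(round(c(seq(4, 21, by = 0.05), times), 6)))
  par <- diurnal_par(
    solar_geometry(grid_times, doy = doy, latitude = latitude,
                   solar_noon = solar_noon),
    par_max = par_max
  )
  truth <- generate_truth(archetypes, layout, nx, ny, times, par,
                          seed = seed, k = k, ...)
  overpasses <- par |>
    dplyr::filter(round(.data$time, 6) %in% round(times, 6)) |>
    dplyr::arrange(.data$time) |>
    dplyr::mutate(overpass = dplyr::row_number())

  by_op <- split(truth, truth$overpass)
  reflectance <- purrr::map(by_op, truth_to_reflectance, mode = mode)
  radiance <- purrr::imap(by_op, function(tr, i) {
    op <- as.integer(i)
    to_at_sensor(reflectance[[i]], tr, atm,
                 distance = distance,
                 ppfd = overpasses$ppfd[op],
                 sif_shape = sif_shape, snr = snr,
                 seed = seed + 1000L + op)
  })

  structure(
    list(truth = truth, par = par, overpasses = overpasses,
         reflectance = reflectance, radiance = radiance,
         atm = atm, layout = layout, archetypes = archetypes,
         config = list(nx = nx, ny = ny, times = times, par_max = par_max,
                       doy = doy, latitude = latitude,
                       solar_noon = solar_noon, distance = distance,
                       snr = snr, mode = mode, seed = seed, k = k)),
    class = "sif_scene"
  )
}

#' @export
print.sif_scene <- function(x, ...) {
  cat(sprintf(
    "<sif_scene> %d x %d pixels, %d overpasses (%s h), mode '%s', snr %s, seed %d\n",
    x$config$nx, x$config$ny, length(x$config$times),
    paste(sprintf("%.2f", x$config$times), collapse = ", "),
    x$config$mode, format(x$config$snr), x$config$seed
  ))
  invisible(x)
}
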