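#' Wavelength-indexed raster stack
#'
#' A `spectral_cube` holds a stack of spatially co-registered spectral bands
#' (radiance or reflectance) as a pixels-by-bands matrix together with the
#' band-centre wavelengths and acquisition metadata. Pixels are stored
#' row-major, north-up, with pixel centres at half-integer grid coordinates
#' (1 m ground sampling distance by convention).
#'
#' @param values Numeric matrix, `nx * ny` rows (pixels, row-major) by
#'   `length(wavelength)` columns (bands).
#' @param wavelength Numeric vector of band-centre wavelengths (nm), strictly
#'   increasing.
#' @param nx,ny Grid dimensions (columns, rows).
#' @param units Character unit string, e.g. `"mW m-2 nm-1 sr-1"` for radiance
#'   or `"1"` for reflectance.
#' @param kind `"radiance"` or `"reflectance"`.
#' @param time Local solar time of acquisition in decimal hours, or `NA`.
#'
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelength, nx, ny,
                          units = "1",
                          kind = c("reflectance", "radiance"),
                          time = NA_real_) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != nx * ny) {
    stop("`values` must have nx * ny = ", nx * ny, " rows, got ", nrow(values))
  }
  if (ncol(values) != length(wavelength)) {
    stop("`values` must have one column per wavelength")
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("`wavelength` must be strictly increasing")
  }
  structure(
    list(
      values = unname(values),
      wavelength = as.numeric(wavelength),
      nx = as.integer(nx), ny = as.integer(ny),
      units = units, kind = kind, time = time
    ),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf(
    "<spectral_cube> %s, %d x %d pixels, %d bands (%.2f-%.2f nm), units '%s'%s\n",
    x$kind, x$nx, x$ny, length(x$wavelength),
    min(x$wavelength), max(x$wavelength), x$units,
    if (is.na(x$time)) "" else sprintf(", t = %.2f h", x$time)
  ))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) c(x$ny, x$nx, length(x$wavelength))

#' Pixel-centre coordinates of a grid
#'
#' Returns one row per pixel in storage (row-major) order, with centres at
#' half-integer coordinates: x increases eastward, y increases southward from
#' the north-west corner.
#'
#' @param nx,ny Grid dimensions.
#' @return A tibble with columns `pixel`, `x`, `y`.
#' @export
grid_pixels <- function(nx, ny) {
  tibble::tibble(
    pixel = seq_len(nx * ny),
    x = rep(seq_len(nx) - 0.5, times = ny),
    y = rep(seq_len(ny) - 0.5, each = nx)
  )
}

#' @rdname grid_pixels
#' @param cube A `spectral_cube`.
#' @export
cube_pixels <- function(cube) grid_pixels(cube$nx, cube$ny)

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format view of a spectral cube
#'
#' @param x A `spectral_cube`.
#' @param ... Unused.
#' @return A tibble with columns `pixel`, `x`, `y`, `wavelength`, `value`
#'   (one row per pixel per band).
#' @export
as_tibble.spectral_cube <- function(x, ...) {
  px <- cube_pixels(x)
  tidyr::crossing(px, wavelength = x$wavelength) |>
    dplyr::arrange(.data$pixel, .data$wavelength) |>
    dplyr::mutate(value = as.vector(t(x$values)))
}

#' Mean reflectance/radiance over a wavelength window
#'
#' Unweighted mean over all band centres falling in the half-open interval
#' `[lo, hi)`. This is the band-averaging convention used for the red and NIR
#' windows of the vegetation indices.
#'
#' @param cube A `spectral_cube`.
#' @param window Numeric length-2 vector `c(lo, hi)` in nm.
#' @return Numeric vector, one value per pixel.
#' @export
band_mean <- function(cube, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- cube$wavelength >= window[1] & cube$wavelength < window[2]
  if (!any(sel)) {
    stop(sprintf("no band centres in window [%g, %g) nm", window[1], window[2]))
  }
  rowMeans(cube$values[, sel, drop = FALSE])
}

#' Band nearest a target wavelength
#'
#' @param cube A `spectral_cube`.
#' @param wavelength Target wavelength (nm).
#' @param tol Maximum allowed distance between the target and the nearest
#'   band centre (nm).
#' @return Numeric vector of the nearest band's values, one per pixel.
#' @export
band_at <- function(cube, wavelength, tol = 5) {
  d <- abs(cube$wavelength - wavelength)
  i <- which.min(d)
  if (d[i] > tol) {
    stop(sprintf("no band centre within %g nm of %g nm (nearest: %g nm)",
                 tol, wavelength, cube$wavelength[i]))
  }
  cube$values[, i]
}
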