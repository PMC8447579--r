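#' Crop archetypes for the scene simulator
#'
#' A crop archetype bundles the per-pixel truth distribution of a crop type:
#' the mean fraction of PAR absorbed by chlorophyll (`fapar_chl_base`), the
#' base escape fraction and its diurnal dynamic, the relative spatial
#' heterogeneity of the truth fields, and the fraction of within-field bare
#' soil pixels (tractor trails, inter-row soil).
#'
#' The diurnal escape-fraction shape encodes the contrasting canopy
#' behaviours: `"ramp"` rises monotonically from the first morning overpass
#' to mid-afternoon and then plateaus (leaf-rosette crops moving from
#' erectophile to planophile orientation), `"constant"` keeps f_esc fixed
#' (spherical, constant leaf angle distribution), and `"midday"` peaks around
#' solar noon (row-planted tree canopies whose lower layers are shaded at
#' noon).
#'
#' @param name Crop label.
#' @param fapar_chl_base Mean fAPAR_chl of vegetated pixels, in (0, 1).
#' @param fesc_base Base escape fraction, in (0, 1].
#' @param fesc_diurnal_amplitude Diurnal f_esc increase, >= 0;
#'   `fesc_base + fesc_diurnal_amplitude` must not exceed 1.
#' @param spatial_heterogeneity Relative standard deviation of the per-pixel
#'   biochemical truth fields (fAPAR_chl, emission efficiency), >= 0.
#' @param fesc_heterogeneity Relative standard deviation of the per-pixel
#'   escape fraction, >= 0. Structural (escape-fraction) variability is
#'   controlled separately from biochemical variability: a homogeneous
#'   cereal canopy has nearly uniform f_esc even where chlorophyll varies,
#'   which is what makes its canopy and leaf SIF maps almost perfectly
#'   correlated, while a mixed-age orchard is dominated by structural
#'   variability.
#' @param soil_fraction Fraction of within-field bare-soil pixels, in \[0, 1).
#' @param fesc_shape One of `"ramp"`, `"constant"`, `"midday"`.
#' @return A one-row tibble.
#' @export
crop_archetype <- function(name, fapar_chl_base, fesc_base,
                           fesc_diurnal_amplitude = 0,
                           spatial_heterogeneity = 0.08,
                           fesc_heterogeneity = spatial_heterogeneity / 2,
                           soil_fraction = 0,
                           fesc_shape = c("ramp", "constant", "midday")) {
  fesc_shape <- match.arg(fesc_shape)
  stopifnot(
    fapar_chl_base > 0, fapar_chl_base < 1,
    fesc_base > 0, fesc_base <= 1,
    fesc_diurnal_amplitude >= 0,
    spatial_heterogeneity >= 0, fesc_heterogeneity >= 0,
    soil_fraction >= 0, soil_fraction < 1
  )
  if (fesc_base + fesc_diurnal_amplitude > 1) {
    stop("fesc_base + fesc_diurnal_amplitude must be <= 1")
  }
  tibble::tibble(
    name = name,
    fapar_chl_base = fapar_chl_base,
    fesc_base = fesc_base,
    fesc_diurnal_amplitude = fesc_diurnal_amplitude,
    spatial_heterogeneity = spatial_heterogeneity,
    fesc_heterogeneity = fesc_heterogeneity,
    soil_fraction = soil_fraction,
    fesc_shape = fesc_shape
  )
}

#' Default crop archetypes
#'
#' Three structurally contrasting crop types: a dense rosette crop with
#' diurnally rising escape fraction (`sugarbeet_like`), a homogeneous cereal
#' with constant escape fraction (`wheat_like`), and a heterogeneous row-tree
#' canopy with a midday escape-fraction peak and appreciable within-parcel
#' soil (`orchard_like`).
#'
#' @return A tibble with one row per archetype.
#' @export
default_archetypes <- function() {
  dplyr::bind_rows(
    crop_archetype("sugarbeet_like", fapar_chl_base = 0.72, fesc_base = 0.62,
                   fesc_diurnal_amplitude = 0.07, spatial_heterogeneity = 0.08,
                   fesc_heterogeneity = 0.03,
                   soil_fraction = 0, fesc_shape = "ramp"),
    crop_archetype("wheat_like", fapar_chl_base = 0.55, fesc_base = 0.55,
                   fesc_diurnal_amplitude = 0, spatial_heterogeneity = 0.06,
                   fesc_heterogeneity = 0.01,
                   soil_fraction = 0.02, fesc_shape = "constant"),
    crop_archetype("orchard_like", fapar_chl_base = 0.45, fesc_base = 0.50,
                   fesc_diurnal_amplitude = 0.08, spatial_heterogeneity = 0.20,
                   fesc_heterogeneity = 0.20,
                   soil_fraction = 0.10, fesc_shape = "midday")
  )
}

#' Field layout
#'
#' A field layout is a tibble with one row per field polygon: field id, crop
#' label and a two-column `polygon` matrix of vertex coordinates (closed
#' implicitly). Pixels outside every polygon are bare soil.
#'
#' @param field Character vector of field ids.
#' @param crop Character vector of crop labels (archetype names).
#' @param polygon List of n-by-2 numeric matrices of vertices (x, y).
#' @return A tibble with columns `field`, `crop`, `polygon`.
#' @export
field_layout <- function(field, crop, polygon) {
  stopifnot(length(field) == length(crop), length(field) == length(polygon))
  ok <- vapply(polygon, function(p) is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3,
               logical(1))
  if (!all(ok)) stop("each polygon must be an n-by-2 matrix with n >= 3")
  tibble::tibble(field = field, crop = crop, polygon = polygon)
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Default rectangular field layout
#'
#' Lays out six rectangular fields (two per archetype) inside a soil margin:
#' a 2 x 3 arrangement with soil strips between fields, so that the scene
#' always contains enough non-vegetated pixels for the retrieval's
#' reference-pixel calibration.
#'
#' @param nx,ny Scene dimensions in pixels.
#' @param crops Character vector of three crop labels filling the six cells.
#' @return A [field_layout()] tibble.
#' @export
default_field_layout <- function(nx, ny,
                                 crops = c("sugarbeet_like", "wheat_like",
                                           "orchard_like")) {
  stopifnot(nx >= 12, ny >= 12, length(crops) == 3)
  mx <- max(2, round(0.08 * nx)); my <- max(2, round(0.08 * ny))
  gap <- max(1, round(0.03 * min(nx, ny)))
  xs <- seq(mx, nx - mx, length.out = 3)    # 2 columns
  ys <- seq(my, ny - my, length.out = 4)    # 3 rows
  cells <- tidyr::crossing(row = 1:3, col = 1:2)
  crop_of_cell <- rep(crops, each = 2)
  polys <- purrr::pmap(cells, function(row, col) {
    rect_poly(xs[col] + gap / 2, ys[row] + gap / 2,
              xs[col + 1] - gap / 2, ys[row + 1] - gap / 2)
  })
  field_layout(
    field = paste0(toupper(substr(crop_of_cell, 1, 2)), "-",
                   rep(1:2, times = 3)),
    crop = crop_of_cell,
    polygon = polys
  )
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised ray-casting containment test used for the pixel-centre-in-
#' polygon rule of the zonal statistics. Points whose ray crosses an even
#' number of edges are outside; points exactly on an edge follow the
#' half-open crossing convention and are treated as outside (boundary
#' tie-break).
#'
#' @param x,y Point coordinates.
#' @param polygon An n-by-2 matrix of polygon vertices.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign pixels to fields
#'
#' Adds `field` and `crop` columns to a pixel table by the
#' pixel-centre-in-polygon rule. Pixels outside every polygon get `NA` field
#' and crop `"soil"`. Overlapping polygons with different crop labels are an
#' error.
#'
#' @param pixels A tibble with `x`, `y` columns (e.g. from [grid_pixels()]).
#' @param layout A [field_layout()] tibble.
#' @return `pixels` with `field` and `crop` columns appended.
#' @export
assign_fields <- function(pixels, layout) {
  field <- rep(NA_character_, nrow(pixels))
  crop <- rep("soil", nrow(pixels))
  for (i in seq_len(nrow(layout))) {
    inside <- point_in_polygon(pixels$x, pixels$y, layout$polygon[[i]])
    clash <- inside & !is.na(field) & crop != layout$crop[i]
    if (any(clash)) {
      stop(sprintf("fields '%s' and '%s' overlap with different crops",
                   field[which(clash)[1]], layout$field[i]))
    }
    field[inside] <- layout$field[i]
    crop[inside] <- layout$crop[i]
  }
  dplyr::mutate(pixels, field = field, crop = crop)
}
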