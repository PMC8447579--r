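#' Read and write spectral cubes
#'
#' Cubes are stored in a two-file plain-text dialect of the classic
#' header + band-sequential raster layout: `<path>.hdr` is a text header
#' with `samples`, `lines`, `bands`, the mandatory `wavelength` list and the
#' acquisition metadata, and `<path>.dat` holds the values in band-sequential
#' order as whitespace-separated ASCII numbers at full double precision. A
#' write-then-read round trip reproduces wavelengths, metadata and values
#' exactly; a header without wavelengths is an error naming the file.
#'
#' @param cube A [spectral_cube()].
#' @param path Path stem (without extension).
#' @return `read_cube()` returns a [spectral_cube()]; `write_cube()`
#'   invisibly returns `path`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  hdr <- c(
    "cube-text 1",
    paste0("samples = ", cube$nx),
    paste0("lines = ", cube$ny),
    paste0("bands = ", length(cube$wavelength)),
    "interleave = bsq",
    paste0("kind = ", cube$kind),
    paste0("units = ", cube$units),
    paste0("time = ", format(cube$time, digits = 17)),
    paste0("wavelength = {",
           paste(format(cube$wavelength, digits = 17, trim = TRUE),
                 collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "w")
  on.exit(close(con))
  # band-sequential: all pixels of band 1, then band 2, ...
  writeLines(format(as.vector(cube$values), digits = 17, trim = TRUE,
                    scientific = TRUE), con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_file <- paste0(path, ".hdr")
  if (!file.exists(hdr_file)) stop("missing header file: ", hdr_file)
  hdr <- readLines(hdr_file)
  get_field <- function(name) {
    line <- grep(paste0("^", name, " ?="), hdr, value = TRUE)
    if (length(line) == 0) return(NULL)
    trimws(sub("^[^=]*= ?", "", line[1]))
  }
  wl_line <- get_field("wavelength")
  if (is.null(wl_line)) {
    stop("header without wavelength metadata: ", hdr_file)
  }
  wavelength <- as.numeric(strsplit(gsub("[{}]", "", wl_line), ",")[[1]])
  nx <- as.integer(get_field("samples"))
  ny <- as.integer(get_field("lines"))
  nb <- as.integer(get_field("bands"))
  vals <- scan(paste0(path, ".dat"), quiet = TRUE)
  if (length(vals) != nx * ny * nb) {
    stop("data file length disagrees with header: ", path)
  }
  spectral_cube(matrix(vals, nrow = nx * ny, ncol = nb),
                wavelength, nx = nx, ny = ny,
                units = get_field("units"),
                kind = get_field("kind"),
                time = as.numeric(get_field("time")))
}

#' Read and write single-band pixel grids
#'
#' Grids travel as CSV with columns `x`, `y`, `value`; the missing-data
#' sentinel is an empty field (read back as `NA`).
#'
#' @param data A tibble with `x`, `y` and a value column.
#' @param value Name of the value column to write.
#' @param path CSV file path.
#' @return `read_grid()` returns a tibble `x`, `y`, `value`.
#' @export
write_grid <- function(data, value, path) {
  data |>
    dplyr::select(dplyr::all_of(c("x", "y", value))) |>
    dplyr::rename(value = dplyr::all_of(value)) |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
}

#' Read and write PAR series
#'
#' The weather-station PAR series travels as CSV with columns `time`,
#' `ppfd`, `par_w`, `par_mw`.
#'
#' @param par A PAR tibble from [diurnal_par()].
#' @param path CSV file path.
#' @return `read_par_csv()` returns the tibble.
#' @export
write_par_csv <- function(par, path) {
  readr::write_csv(
    dplyr::select(par, dplyr::any_of(c("time", "ppfd", "par_w", "par_mw"))),
    path
  )
  invisible(path)
}

#' @rdname write_par_csv
#' @export
read_par_csv <- function(path) {
  if (!file.exists(path)) stop("missing PAR series file: ", path)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
}

#' Read and write field layouts as GeoJSON
#'
#' Field polygons travel as a GeoJSON FeatureCollection of Polygon features
#' with `field` and `crop` properties.
#'
#' @param layout A [field_layout()] tibble.
#' @param path GeoJSON file path.
#' @return `read_layout_geojson()` returns a [field_layout()] tibble.
#' @export
write_layout_geojson <- function(layout, path) {
  features <- purrr::pmap(layout, function(field, crop, polygon) {
    ring <- rbind(polygon, polygon[1, , drop = FALSE]) # closed ring
    list(
      type = "Feature",
      properties = list(field = field, crop = crop),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- purrr::map(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE] # drop closing vertex
    list(field = f$properties$field, crop = f$properties$crop, polygon = ring)
  })
  field_layout(
    field = purrr::map_chr(rows, "field"),
    crop = purrr::map_chr(rows, "crop"),
    polygon = purrr::map(rows, "polygon")
  )
}

run_config_defaults <- function() {
  list(
    seed = 1L, nx = 64L, ny = 64L,
    alpha = 0.1, k = 0.79, fcvi_min = 0.18, ndvi_ref_max = 0.1,
    ppfd_to_w = 0.219,
    times = default_overpass_times(),
    par_max = 438, distance = 1, snr = Inf, mode = "consistent",
    fit_window = c(750, 778), poly_degree = 2L,
    sif_peak = 740, sif_sigma = 25,
    d_npq = 0.3, eps_max = 1e-4
  )
}

#' Pipeline run configuration
#'
#' Assembles, validates and round-trips the configuration of a full pipeline
#' run: the scene size and seed, the index constants (`alpha`, `k`), the
#' validity thresholds (`fcvi_min`, `ndvi_ref_max`), the PPFD-to-W
#' conversion factor, the overpass times and the simulator/retrieval
#' settings. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$alpha > 0, cfg$k > 0, cfg$k <= 1,
            cfg$fcvi_min >= 0, cfg$ndvi_ref_max >= 0,
            cfg$ppfd_to_w > 0, cfg$nx >= 12, cfg$ny >= 12,
            length(cfg$times) >= 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$snr <- if (is.character(vals$snr)) Inf else vals$snr
  do.call(run_config, vals)
}

#' Run manifest
#'
#' Records the provenance of a pipeline run: configuration hash, seed,
#' package version and timestamp, as JSON.
#'
#' @param cfg A [run_config()].
#' @param path JSON file path, or `NULL` to return the manifest only.
#' @return The manifest list, invisibly when written.
#' @export
write_manifest <- function(cfg, path = NULL) {
  manifest <- list(
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package = "sifdown",
    version = as.character(utils::packageVersion("sifdown")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
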