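#' Per-field diurnal summary statistics
#'
#' Zonal percentile boxes over the valid pixels of each field and overpass:
#' for every requested variable, the 0th, 25th, 50th, 75th and 100th
#' percentiles (linear interpolation between order statistics), the mean,
#' standard deviation and valid-pixel count. Fields with zero valid pixels
#' for a variable are omitted with a warning.
#'
#' @param data A pixel table with `field`, `crop`, and the variable columns;
#'   one overpass per distinct value of the grouping columns in `by`.
#' @param vars Character vector of variable columns to summarize.
#' @param by Grouping columns identifying an overpass, default
#'   `c("overpass", "time")` (intersected with the table's columns).
#' @param valid Optional name of a logical validity-mask column; invalid
#'   pixels are dropped before summarizing.
#' @return A tibble with one row per field x overpass x variable:
#'   `field`, `crop`, grouping columns, `variable`, `p0`, `p25`, `p50`,
#'   `p75`, `p100`, `mean`, `sd`, `n`.
#' @export
field_stats <- function(data, vars, by = c("overpass", "time"),
                        valid = NULL) {
  by <- intersect(by, names(data))
  stopifnot(all(vars %in% names(data)), "field" %in% names(data))
  all_fields <- data |>
    dplyr::filter(!is.na(.data$field)) |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(c("field", by)))) |>
    nrow()
  if (!is.null(valid)) data <- data[data[[valid]] %in% TRUE, , drop = FALSE]
  long <- data |>
    dplyr::filter(!is.na(.data$field)) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable",
                        values_to = ".value") |>
    dplyr::filter(!is.na(.data$.value))
  out <- long |>
    dplyr::summarise(
      p0 = unname(stats::quantile(.data$.value, 0, type = 7)),
      p25 = unname(stats::quantile(.data$.value, 0.25, type = 7)),
      p50 = unname(stats::quantile(.data$.value, 0.50, type = 7)),
      p75 = unname(stats::quantile(.data$.value, 0.75, type = 7)),
      p100 = unname(stats::quantile(.data$.value, 1, type = 7)),
      mean = mean(.data$.value),
      sd = stats::sd(.data$.value),
      n = dplyr::n(),
      .by = dplyr::all_of(c("field", "crop", by, "variable"))
    )
  expected <- long |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(c("field", by)))) |>
    nrow()
  if (all_fields > expected) {
    warning(all_fields - expected,
            " field-overpass combinations had no valid pixels and were omitted")
  }
  out
}

#' Canopy-leaf SIF pixel correlation per field
#'
#' Pearson correlation between canopy and leaf SIF760 over the corresponding
#' valid pixels of each field and overpass. Fields with fewer than three
#' valid pixels, or with zero variance in either map, yield a missing
#' correlation with a flag.
#'
#' @param data Pixel table with `field`, `crop`, `sif_canopy`, `sif_leaf`
#'   columns (plus overpass grouping columns).
#' @param by Grouping columns identifying an overpass.
#' @param valid Optional name of a logical validity-mask column.
#' @return A tibble: `field`, `crop`, grouping columns, `r`, `n`, `flag`
#'   (`"ok"`, `"n_lt_3"` or `"zero_variance"`).
#' @export
canopy_leaf_correlation <- function(data, by = c("overpass", "time"),
                                    valid = "valid") {
  by <- intersect(by, names(data))
  if (!is.null(valid) && valid %in% names(data)) {
    data <- data[data[[valid]] %in% TRUE, , drop = FALSE]
  }
  data |>
    dplyr::filter(!is.na(.data$field),
                  !is.na(.data$sif_canopy), !is.na(.data$sif_leaf)) |>
    dplyr::summarise(
      n = dplyr::n(),
      flag = dplyr::case_when(
        n < 3 ~ "n_lt_3",
        stats::sd(.data$sif_canopy) == 0 |
          stats::sd(.data$sif_leaf) == 0 ~ "zero_variance",
        .default = "ok"
      ),
      r = ifelse(flag == "ok",
                 stats::cor(.data$sif_canopy, .data$sif_leaf), NA_real_),
      .by = dplyr::all_of(c("field", "crop", by))
    )
}

#' Crop-level correlation aggregation
#'
#' Aggregates field-level canopy-leaf correlations to crop level, per
#' overpass: the unweighted mean and standard deviation of the field
#' correlation coefficients (the default convention), or a single
#' pixel-pooled correlation when `pooled = TRUE` requires re-supplying the
#' pixel table.
#'
#' @param correlations Output of [canopy_leaf_correlation()].
#' @param by Grouping columns identifying an overpass.
#' @return A tibble: `crop`, grouping columns, `r_mean`, `r_sd`, `n_fields`.
#' @export
correlation_by_crop <- function(correlations, by = c("overpass", "time")) {
  by <- intersect(by, names(correlations))
  correlations |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::summarise(
      r_mean = mean(.data$r),
      r_sd = stats::sd(.data$r),
      n_fields = dplyr::n(),
      .by = dplyr::all_of(c("crop", by))
    )
}

#' Diurnal efficiency-light hysteresis series
#'
#' Builds, per crop, the chronologically ordered sequence of
#' (driver mean, efficiency mean +/- sd) pairs over valid pixels, from which
#' the morning and afternoon branches of the efficiency-light relationship
#' can be compared. The driver is PAR (for `eps_par`) or APAR_chl (for the
#' FCVI-based efficiency).
#'
#' @param data Pixel table with `crop`, `time`, the efficiency column and
#'   the driver column.
#' @param eps Name of the efficiency column, default `"eps_fcvi"`.
#' @param driver Name of the driver column, default `"apar_chl"`.
#' @param valid Optional name of a logical validity-mask column.
#' @return A tibble of class `sif_hysteresis`: `crop`, `time`,
#'   `driver_mean`, `eps_mean`, `eps_sd`, `n`, ordered by time within crop.
#' @export
hysteresis <- function(data, eps = "eps_fcvi", driver = "apar_chl",
                       valid = "valid") {
  stopifnot(all(c("crop", "time", eps, driver) %in% names(data)))
  if (!is.null(valid) && valid %in% names(data)) {
    data <- data[data[[valid]] %in% TRUE, , drop = FALSE]
  }
  n_op <- length(unique(data$time))
  if (n_op < 2) {
    stop("hysteresis needs at least two overpasses, got ", n_op)
  }
  out <- data |>
    dplyr::filter(!is.na(.data[[eps]]), !is.na(.data[[driver]])) |>
    dplyr::summarise(
      driver_mean = mean(.data[[driver]]),
      eps_mean = mean(.data[[eps]]),
      eps_sd = stats::sd(.data[[eps]]),
      n = dplyr::n(),
      .by = dplyr::all_of(c("crop", "time"))
    ) |>
    dplyr::arrange(.data$crop, .data$time)
  if (any(out$driver_mean < 0)) stop("negative driver values in hysteresis")
  class(out) <- c("sif_hysteresis", class(out))
  out
}
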