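#' SIF emission-efficiency normalizations
#'
#' Three normalizations of leaf-level SIF that remove the effect of incoming
#' radiation (all in nm-1, PAR as a scene scalar per overpass in mW m-2):
#'
#' * `eps_par()`: `SIF760_leaf / PAR` — apparent emission efficiency per
#'   unit total incoming PAR.
#' * `eps_aparchl()`: `SIF760_leaf / (fAPAR_chl * PAR)` — efficiency per
#'   unit PAR absorbed by chlorophyll.
#' * `eps_fcvi()`: `pi * SIF760_canopy / (FCVI * PAR)` — algebraically
#'   identical to `eps_aparchl()` when the escape fraction comes from the
#'   FCVI ratio (fAPAR_chl cancels), but computable without knowing
#'   fAPAR_chl, f_esc or leaf SIF.
#'
#' @param sif_leaf Leaf SIF760 (mW m-2 nm-1).
#' @param sif_canopy Canopy SIF760 (mW m-2 nm-1 sr-1).
#' @param fapar_chl fAPAR_chl values, > 0 on valid pixels.
#' @param fcvi FCVI values, > 0 on valid pixels.
#' @param par_mw Overpass PAR (mW m-2, scalar > 0).
#' @return Numeric vector of efficiencies (nm-1).
#' @examples
#' eps_par(10, 1e5)           # 1e-4
#' eps_aparchl(10, 0.5, 1e5)  # 2e-4
#' @export
eps_par <- function(sif_leaf, par_mw) {
  if (!is.numeric(par_mw) || any(par_mw <= 0)) stop("`par_mw` must be > 0")
  sif_leaf / par_mw
}

#' @rdname eps_par
#' @export
eps_aparchl <- function(sif_leaf, fapar_chl, par_mw) {
  if (!is.numeric(par_mw) || any(par_mw <= 0)) stop("`par_mw` must be > 0")
  if (any(!is.na(sif_leaf) & (is.na(fapar_chl) | fapar_chl <= 0))) {
    stop("`fapar_chl` must be positive wherever leaf SIF is defined")
  }
  sif_leaf / (fapar_chl * par_mw)
}

#' @rdname eps_par
#' @export
eps_fcvi <- function(sif_canopy, fcvi, par_mw) {
  if (!is.numeric(par_mw) || any(par_mw <= 0)) stop("`par_mw` must be > 0")
  if (any(!is.na(sif_canopy) & !is.na(fcvi) & fcvi <= 0)) {
    stop("`fcvi` must be positive on valid pixels")
  }
  pi * sif_canopy / (fcvi * par_mw)
}

#' Emission-efficiency maps over a downscaled pixel table
#'
#' Appends the three efficiency variants to a table produced by
#' [downscale_sif()] (columns `sif_leaf`, `sif_canopy`, `fapar_chl`,
#' `fcvi`, `valid`). Efficiencies are computed on valid pixels and missing
#' elsewhere.
#'
#' @param data A downscaled pixel table.
#' @param par_mw Overpass PAR (mW m-2, scalar > 0).
#' @return `data` with `eps_par`, `eps_aparchl`, `eps_fcvi` appended.
#' @export
emission_efficiency <- function(data, par_mw) {
  v <- data$valid
  data |>
    dplyr::mutate(
      eps_par = ifelse(v, eps_par(.data$sif_leaf, par_mw), NA_real_),
      eps_aparchl = ifelse(
        v, eps_aparchl(ifelse(v, .data$sif_leaf, NA_real_),
                       .data$fapar_chl, par_mw), NA_real_),
      eps_fcvi = ifelse(
        v, eps_fcvi(.data$sif_canopy, ifelse(v, .data$fcvi, NA_real_),
                    par_mw), NA_real_)
    )
}
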