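#' Per-pixel scene truth for a diurnal multi-overpass simulation
#'
#' Draws per-pixel canopy truth around the crop-archetype bases and evolves
#' it over the overpass times:
#'
#' * `fapar_chl` and the base escape fraction are drawn per pixel with the
#'   archetype's relative spatial heterogeneity (clamped to valid ranges) and
#'   held fixed in time; `fapar_green = fapar_chl / k`.
#' * `fesc(t)` follows the archetype's diurnal shape: a monotone
#'   morning-to-mid-afternoon ramp (plateau after ~14:40), a constant, or a
#'   solar-noon-centred bump.
#' * The emission efficiency follows a saturating light response with an
#'   NPQ-like afternoon depression,
#'   `eps(t) = eps_max * (1 - d_npq * H(t)) * PAR / (PAR + light_half_sat)`,
#'   where `H(t)` is the normalized PAR history passed through a first-order
#'   low-pass filter with time constant `npq_tau` (hours). The lag makes eps
#'   versus PAR trace a hysteresis loop with the afternoon branch below the
#'   morning branch; `d_npq = 0` removes the loop.
#' * Leaf and canopy SIF close the chain exactly:
#'   `sif_leaf = eps * fapar_chl * par_mw` (mW m-2 nm-1, hemispherical) and
#'   `sif_canopy = fesc * sif_leaf / pi` (mW m-2 nm-1 sr-1, directional).
#'
#' Bare-soil pixels (outside every field polygon, plus the archetype's
#' `soil_fraction` within fields) carry zero fAPAR and SIF and `NA` escape
#' fraction.
#'
#' @param archetypes Archetype tibble, e.g. [default_archetypes()].
#' @param layout Field layout, e.g. [default_field_layout()].
#' @param nx,ny Scene dimensions in pixels.
#' @param times Overpass times (decimal hours); must be present in
#'   `par$time`.
#' @param par PAR series from [diurnal_par()] on a time grid covering the
#'   diurnal course (used both for the overpass PAR and the lagged history).
#' @param seed Integer seed; a fixed seed gives bit-identical truth.
#' @param k Ratio fAPAR_chl / fAPAR_green (default 0.79).
#' @param eps_max Maximum emission efficiency (nm-1), default 1e-4.
#' @param d_npq Afternoon depression depth in \[0, 1\], default 0.3.
#' @param npq_tau Time constant of the PAR-history filter (h), default 2.5.
#' @param light_half_sat Half-saturation of the efficiency light response
#'   (mW m-2), default 1.5e5.
#' @return A tibble with one row per pixel per overpass: `overpass`, `time`,
#'   `pixel`, `x`, `y`, `field`, `crop`, `soil`, `par_mw`, `fapar_green`,
#'   `fapar_chl`, `fesc`, `eps_true`, `sif_leaf`, `sif_canopy`.
#' @export
generate_truth <- function(archetypes, layout, nx, ny, times, par, seed,
                           k = 0.79, eps_max = 1e-4, d_npq = 0.3,
                           npq_tau = 2.5, light_half_sat = 1.5e5) {
  stopifnot(is.data.frame(par), all(c("time", "par_mw") %in% names(par)))
  miss <- setdiff(round(times, 6), round(par$time, 6))
  if (length(miss) > 0) {
    stop("overpass times missing from the PAR series: ",
         paste(format(miss), collapse = ", "))
  }
  px <- assign_fields(grid_pixels(nx, ny), layout)
  unknown <- setdiff(setdiff(unique(px$crop), "soil"), archetypes$name)
  if (length(unknown) > 0) {
    stop("layout crops without an archetype: ", paste(unknown, collapse = ", "))
  }

  set.seed(seed)
  n <- nrow(px)
  arch_idx <- match(px$crop, archetypes$name)          # NA for soil
  base_f <- archetypes$fapar_chl_base[arch_idx]
  base_e <- archetypes$fesc_base[arch_idx]
  amp <- archetypes$fesc_diurnal_amplitude[arch_idx]
  het <- archetypes$spatial_heterogeneity[arch_idx]
  fesc_het <- archetypes$fesc_heterogeneity[arch_idx]
  shape <- archetypes$fesc_shape[arch_idx]

  # static per-pixel draws, clamped to ranges the reflectance construction
  # can invert (fapar_green = fapar_chl / k stays in the linear fAPAR range);
  # soil placeholders keep the draw count fixed and are overwritten below
  bf <- dplyr::coalesce(base_f, 0.5); be <- dplyr::coalesce(base_e, 0.5)
  am <- dplyr::coalesce(amp, 0); ht <- dplyr::coalesce(het, 0)
  eht <- dplyr::coalesce(fesc_het, 0)
  fapar_chl <- pmin(pmax(stats::rnorm(n, bf, bf * ht), 0.30), 0.785)
  fesc0 <- pmin(pmax(stats::rnorm(n, be, be * eht), 0.05), 1 - am)
  eps_mult <- pmin(pmax(stats::rnorm(n, 1, ht / 2), 0.5), 1.5)

  # within-field bare-soil pixels
  soil <- is.na(arch_idx)
  for (i in seq_len(nrow(archetypes))) {
    sf <- archetypes$soil_fraction[i]
    if (sf > 0) {
      in_crop <- which(!soil & px$crop == archetypes$name[i])
      n_soil <- round(sf * length(in_crop))
      if (n_soil > 0) soil[sample(in_crop, n_soil)] <- TRUE
    }
  }
  fapar_chl[soil] <- 0
  fesc0[soil] <- NA_real_
  eps_mult[soil] <- 0

  # NPQ-like lagged PAR history on the full series grid
  ord <- order(par$time)
  pt <- par$time[ord]; pp <- par$par_mw[ord]
  p_norm <- if (max(pp) > 0) pp / max(pp) else pp
  h <- numeric(length(pt))
  for (i in seq_along(pt)[-1]) {
    a <- 1 - exp(-(pt[i] - pt[i - 1]) / npq_tau)
    h[i] <- h[i - 1] + a * (p_norm[i - 1] - h[i - 1])
  }

  smoothstep <- function(u) { u <- pmin(pmax(u, 0), 1); u^2 * (3 - 2 * u) }
  diurnal_gain <- function(shape, time) {
    dplyr::case_when(
      shape == "ramp" ~ smoothstep((time - 10.17) / (14.67 - 10.17)),
      shape == "midday" ~ exp(-(time - 13.5)^2 / (2 * 1.8^2)),
      .default = 0
    )
  }

  per_overpass <- purrr::imap(times, function(t, i) {
    j <- which.min(abs(pt - t))
    par_mw_t <- pp[j]
    eps_t <- eps_max * (1 - d_npq * h[j]) *
      par_mw_t / (par_mw_t + light_half_sat)
    fesc_t <- fesc0 + amp * diurnal_gain(shape, t)
    eps_pix <- eps_t * eps_mult
    sif_leaf <- eps_pix * fapar_chl * par_mw_t
    sif_canopy <- ifelse(soil, 0, fesc_t * sif_leaf / pi)
    dplyr::mutate(
      px,
      overpass = i, time = t, par_mw = par_mw_t,
      soil = soil,
      fapar_chl = fapar_chl,
      fapar_green = fapar_chl / k,
      fesc = ifelse(soil, NA_real_, fesc_t),
      eps_true = eps_pix,
      sif_leaf = ifelse(soil, 0, sif_leaf),
      sif_canopy = sif_canopy,
      .before = 1
    )
  })
  dplyr::bind_rows(per_overpass) |>
    dplyr::relocate(dplyr::all_of(c("overpass", "time", "pixel", "x", "y",
                                    "field", "crop", "soil")))
}
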