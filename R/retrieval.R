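#' SFM retrieval configuration
#'
#' Settings of the spectral-fitting-method retrieval: the fit window around
#' the O2-A band, the degree of the reflectance polynomial, the fixed SIF
#' spectral shape with one free amplitude, the NDVI threshold identifying
#' non-vegetated reference pixels, the distance-scale search grid, the
#' negative-amplitude floor, and the seeded reference-subsample cap.
#'
#' @param window Fit window (nm), default c(750, 778): the O2-A band core
#'   and its red wing plus continuum on both sides; must contain 760 nm.
#' @param poly_degree Reflectance polynomial degree, default 2.
#' @param sif_shape SIF shape from [sif_spectrum()].
#' @param ndvi_reference_max NDVI threshold for reference pixels
#'   (inclusive), default 0.1.
#' @param distance_grid Distance-scale grid for the calibration search.
#' @param a_floor Negative-SIF floor (mW m-2 nm-1 sr-1): retrieved
#'   amplitudes below `-a_floor` are flagged as failed, default 1.
#' @param ref_subsample Maximum number of reference pixels used in the
#'   calibration (seeded subsample), default 2000.
#' @param calibration_tol Absolute mean reference SIF above which the
#'   calibration is flagged poor, default 0.01.
#' @param fwhm,band_step Instrument response assumed by the forward model in
#'   the fit, matching the simulator defaults.
#' @param seed Seed for the reference subsample.
#' @return A list of class `retrieval_config`.
#' @export
retrieval_config <- function(window = c(750, 778), poly_degree = 2,
                             sif_shape = sif_spectrum(),
                             ndvi_reference_max = 0.1,
                             distance_grid = seq(0.6, 1.4, by = 0.05),
                             a_floor = 1, ref_subsample = 2000,
                             calibration_tol = 0.01,
                             fwhm = 0.28, band_step = 0.11, seed = 1) {
  stopifnot(window[1] < 760, window[2] > 760, poly_degree >= 0,
            a_floor >= 0, ref_subsample >= 1)
  structure(
    list(window = window, poly_degree = poly_degree, sif_shape = sif_shape,
         ndvi_reference_max = ndvi_reference_max,
         distance_grid = sort(distance_grid), a_floor = a_floor,
         ref_subsample = ref_subsample, calibration_tol = calibration_tol,
         fwhm = fwhm, band_step = band_step, seed = seed),
    class = "retrieval_config"
  )
}

#' Select non-vegetated reference pixels
#'
#' Identifies the non-fluorescent pixels used to calibrate the effective
#' surface-sensor distance: all pixels with NDVI at or below the threshold
#' (the threshold itself is included). NDVI is computed from the companion
#' reflectance cube's 665-680 nm and 795-810 nm band means; when no
#' reflectance cube is available, a radiance-ratio proxy over the edges of
#' the radiance cube's own range is used instead (a documented dialect
#' difference).
#'
#' @param radiance Radiance [spectral_cube()].
#' @param reflectance Companion reflectance cube, or `NULL` for the
#'   radiance proxy.
#' @param ndvi_max Inclusive NDVI threshold, default 0.1.
#' @return A tibble with columns `pixel` and `ndvi` of the selected pixels.
#' @export
select_reference_pixels <- function(radiance, reflectance = NULL,
                                    ndvi_max = 0.1) {
  if (!is.null(reflectance)) {
    nir <- band_mean(reflectance, c(795, 810))
    red <- band_mean(reflectance, c(665, 680))
  } else {
    lo <- min(radiance$wavelength); hi <- max(radiance$wavelength)
    nir <- band_mean(radiance, c(hi - 10, hi + 1e-9))
    red <- band_mean(radiance, c(lo, lo + 10))
  }
  nd <- ndvi(nir, red)
  sel <- which(!is.na(nd) & nd <= ndvi_max)
  if (length(sel) == 0) {
    stop("no reference pixels with NDVI <= ", ndvi_max,
         ": widen the scene or raise the threshold; ",
         "distance calibration is impossible")
  }
  tibble::tibble(pixel = sel, ndvi = nd[sel])
}

# Design matrix of the linearised SFM model on the sensor band grid:
# columns are the instrument-convolved fine-grid basis
#   E_g T_down T_up / pi * ((wl - 760)/10)^j   (reflectance polynomial)
#   g(wl) T_up                                 (SIF amplitude; g(760) = 1)
# plus the known path-radiance term returned separately for subtraction.
sfm_design <- function(atm, d, cfg, band_centres, e_scale = 1) {
  wl <- atm$wavelength
  srf <- gaussian_srf_matrix(band_centres, wl, cfg$fwhm)
  refl_gain <- atm$e_ground * e_scale * atm_t_down(atm, d) *
    atm_t_up(atm, d) / pi
  u <- (wl - 760) / 10
  poly_cols <- vapply(0:cfg$poly_degree,
                      function(j) refl_gain * u^j, numeric(length(wl)))
  sif_col <- cfg$sif_shape(wl) * atm_t_up(atm, d)
  x <- srf %*% cbind(poly_cols, sif_col)
  colnames(x) <- c(paste0("a", 0:cfg$poly_degree), "sif")
  list(x = x, path = as.vector(srf %*% atm_l_path(atm, d)))
}

# Identifiability of the SIF amplitude: fraction of the SIF column's norm
# orthogonal to the polynomial columns. Without the absorption band the SIF
# shape is nearly polynomial over the window and the fraction collapses.
sif_identifiability <- function(x) {
  p <- x[, -ncol(x), drop = FALSE]
  s <- x[, ncol(x)]
  resid <- s - p %*% qr.coef(qr(p), s)
  sqrt(sum(resid^2) / sum(s^2))
}

# Weighted linear least squares across a block of pixels. The sensor noise
# model is multiplicative (per-band SD proportional to the signal), so bands
# inside the absorption trough -- where the radiance and hence the noise are
# small but the fluorescence in-filling is most informative -- get large
# weights. Weights are per pixel (each pixel's own spectrum estimates its
# noise), solved by vectorised normal equations: the design is small (a few
# polynomial coefficients plus the SIF amplitude), so the per-pixel
# cross-products reduce to one matrix product over the block. On noise-free
# input the weights cancel and the fit is exact.
fit_sfm_block <- function(spectra, design, a_floor, min_identifiability = 0.05) {
  n <- nrow(spectra)
  x <- design$x
  p <- ncol(x)
  mean_w <- 1 / pmax(colMeans(abs(spectra)), 1e-9)
  ident <- sif_identifiability(x * mean_w)
  if (!is.finite(ident) || ident < min_identifiability ||
      qr(x * mean_w)$rank < p) {
    return(tibble::tibble(sif760 = rep(NA_real_, n),
                          reflectance760 = NA_real_,
                          rms = NA_real_, flag = "failed"))
  }
  y <- spectra - rep(design$path, each = n)         # n x nb
  # first pass: unweighted fit; its fitted values estimate the noise-free
  # signal, from which the per-band precision weights follow without the
  # weight-noise correlation that raw-spectrum weights would introduce
  beta0 <- qr.coef(qr(x), t(y))                     # p x n
  fitted0 <- t(x %*% beta0) + rep(design$path, each = n)
  w <- 1 / pmax(abs(fitted0), 1e-9)^2               # n x nb precision weights
  # second pass, normal equations per pixel: (X' W_i X) b_i = X' W_i y_i
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  xtx_basis <- x[, pairs[, 1], drop = FALSE] * x[, pairs[, 2], drop = FALSE]
  xtx <- w %*% xtx_basis                            # n x p(p+1)/2
  xty <- (w * y) %*% x                              # n x p
  coef <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(x)))
  a_full <- matrix(0, p, p)
  idx <- cbind(pairs[, 1], pairs[, 2])
  for (i in seq_len(n)) {
    a_full[idx] <- xtx[i, ]
    a_full[idx[, 2:1]] <- xtx[i, ]
    beta <- tryCatch(solve(a_full, xty[i, ]), error = function(e) NULL)
    if (!is.null(beta)) coef[i, ] <- unname(beta)
  }
  resid <- y - coef %*% t(x)
  sif <- unname(coef[, "sif"])
  rms <- sqrt(rowMeans(resid^2))
  ok <- is.finite(sif) & sif >= -a_floor
  tibble::tibble(
    sif760 = ifelse(ok, sif, NA_real_),
    reflectance760 = ifelse(ok, coef[, "a0"], NA_real_),
    rms = rms,
    flag = ifelse(ok, "converged", "failed")
  )
}

#' Fit the SFM model to a single spectrum
#'
#' Least-squares decoupling of reflectance and fluorescence for one pixel:
#' the at-sensor radiance over the fit window is modelled as
#' `E_g T_down R_poly T_up / pi + A g T_up + L_path` with the polynomial
#' coefficients and the SIF amplitude `A` free (small negative amplitudes
#' down to `-a_floor` are permitted to avoid truncation bias). The model is
#' linear in its free parameters, so the fit is solved exactly by QR
#' factorization; the flag is `"failed"` when the design is rank-deficient,
#' the SIF amplitude is unidentifiable (no absorption band in the window),
#' or the amplitude falls below the floor — outputs are then missing, never
#' silently zero.
#'
#' @param spectrum Radiance spectrum over (at least) the fit window.
#' @param wavelength Band centres of `spectrum` (nm).
#' @param atm An [atmospheric_table()].
#' @param d Distance scale at which to evaluate the atmosphere.
#' @param cfg A [retrieval_config()].
#' @param e_scale Irradiance scale of the overpass relative to
#'   `atm$e_ref_ppfd`.
#' @return A one-row tibble: `sif760`, `reflectance760`, `rms`, `flag`.
#' @export
fit_pixel <- function(spectrum, wavelength, atm, d, cfg = retrieval_config(),
                      e_scale = 1) {
  stopifnot(length(spectrum) == length(wavelength))
  if (any(!is.finite(spectrum))) {
    return(tibble::tibble(sif760 = NA_real_, reflectance760 = NA_real_,
                          rms = NA_real_, flag = "failed"))
  }
  inw <- wavelength >= cfg$window[1] & wavelength <= cfg$window[2]
  if (!any(inw)) stop("fit window outside the spectrum's wavelength range")
  design <- sfm_design(atm, d, cfg, wavelength[inw], e_scale)
  fit_sfm_block(matrix(spectrum[inw], nrow = 1), design, cfg$a_floor)
}

#' Calibrate the effective surface-sensor distance
#'
#' Scans the configured distance grid, retrieves SIF for a (seeded)
#' subsample of the non-vegetated reference pixels at each grid point, and
#' returns the distance minimizing the absolute mean reference SIF, refined
#' parabolically between grid points. Non-vegetated surfaces emit no
#' fluorescence, so the correct absorption-path scale is the one whose
#' retrieval returns zero SIF over them.
#'
#' @param radiance Radiance [spectral_cube()].
#' @param refs Reference-pixel tibble from [select_reference_pixels()].
#' @param atm An [atmospheric_table()].
#' @param cfg A [retrieval_config()].
#' @param e_scale Irradiance scale of the overpass.
#' @return A list: `d_star`, `mean_ref_sif` (at `d_star`), `n_ref`,
#'   `poor_calibration` flag, and the `profile` tibble of the grid scan
#'   (`d`, `mean_sif`).
#' @export
calibrate_effective_distance <- function(radiance, refs, atm,
                                         cfg = retrieval_config(),
                                         e_scale = 1) {
  if (nrow(refs) == 0) stop("empty reference set")
  set.seed(cfg$seed)
  use <- refs$pixel
  if (length(use) > cfg$ref_subsample) {
    use <- sort(sample(use, cfg$ref_subsample))
  }
  inw <- radiance$wavelength >= cfg$window[1] &
    radiance$wavelength <= cfg$window[2]
  spectra <- radiance$values[use, inw, drop = FALSE]
  bands <- radiance$wavelength[inw]

  mean_sif_at <- function(d) {
    design <- sfm_design(atm, d, cfg, bands, e_scale)
    mean(fit_sfm_block(spectra, design, a_floor = Inf)$sif760)
  }
  grid <- cfg$distance_grid
  ms <- vapply(grid, mean_sif_at, numeric(1))
  i <- which.min(abs(ms))
  d_star <- grid[i]
  mean_at_star <- ms[i]
  # The mean reference SIF crosses zero almost linearly in d while |mean SIF|
  # is V-shaped, so the refinement between grid points is a root search on
  # the signed mean (a parabolic step on |mean| is the fallback when the
  # grid scan shows no sign change). The retrieved SIF is steeply sensitive
  # to the distance scale, so the root is polished well below the grid step.
  sign_change <- which(diff(sign(ms)) != 0)
  if (length(sign_change) > 0) {
    j <- sign_change[which.min(abs(ms[sign_change]))]
    root <- stats::uniroot(mean_sif_at, lower = grid[j], upper = grid[j + 1],
                           f.lower = ms[j], f.upper = ms[j + 1],
                           tol = 1e-7)
    d_star <- root$root
    mean_at_star <- root$f.root
  } else if (i > 1 && i < length(grid)) {
    y <- abs(ms[(i - 1):(i + 1)])
    denom <- y[1] - 2 * y[2] + y[3]
    if (is.finite(denom) && denom > 0) {
      step <- grid[i + 1] - grid[i]
      d_ref <- grid[i] + 0.5 * step * (y[1] - y[3]) / denom
      m_ref <- mean_sif_at(d_ref)
      if (abs(m_ref) < abs(mean_at_star)) {
        d_star <- d_ref
        mean_at_star <- m_ref
      }
    }
  }
  list(
    d_star = d_star,
    mean_ref_sif = mean_at_star,
    n_ref = length(use),
    poor_calibration = abs(mean_at_star) > cfg$calibration_tol,
    profile = tibble::tibble(d = grid, mean_sif = ms)
  )
}

#' Retrieve SIF760 for a whole scene
#'
#' Composes the three SFM steps — reference-pixel selection, effective-
#' distance calibration, and per-pixel spectral fitting — over all pixels of
#' a radiance cube. The per-pixel fits share one design matrix (the model is
#' linear in its free parameters), so the scene retrieval is a single
#' vectorised least-squares solve.
#'
#' @param radiance Radiance [spectral_cube()].
#' @param reflectance Companion reflectance cube for NDVI-based reference
#'   selection, or `NULL` to use the radiance proxy.
#' @param atm An [atmospheric_table()].
#' @param cfg A [retrieval_config()].
#' @param e_scale Irradiance scale of the overpass relative to
#'   `atm$e_ref_ppfd` (e.g. `ppfd / 2000`).
#' @return An object of class `sfm_retrieval`: `map` (tibble with `pixel`,
#'   `x`, `y`, `sif760`, `reflectance760`, `rms`, `flag` where `flag` is
#'   `"converged"`, `"failed"` or `"reference"`), `calibration` (the
#'   [calibrate_effective_distance()] result), `config`, and the acquisition
#'   `time`.
#' @export
retrieve_scene <- function(radiance, reflectance = NULL, atm,
                           cfg = retrieval_config(), e_scale = 1) {
  refs <- select_reference_pixels(radiance, reflectance,
                                  cfg$ndvi_reference_max)
  cal <- calibrate_effective_distance(radiance, refs, atm, cfg, e_scale)

  inw <- radiance$wavelength >= cfg$window[1] &
    radiance$wavelength <= cfg$window[2]
  design <- sfm_design(atm, cal$d_star, cfg, radiance$wavelength[inw], e_scale)
  fits <- fit_sfm_block(radiance$values[, inw, drop = FALSE], design,
                        cfg$a_floor)
  map <- dplyr::bind_cols(cube_pixels(radiance), fits) |>
    dplyr::mutate(flag = ifelse(.data$pixel %in% refs$pixel & .data$flag ==
                                  "converged", "reference", .data$flag))
  structure(
    list(map = map, calibration = cal, config = cfg, time = radiance$time),
    class = "sfm_retrieval"
  )
}

#' @export
print.sfm_retrieval <- function(x, ...) {
  cat(sprintf(
    "<sfm_retrieval> %d pixels, d* = %.4f, mean reference SIF = %.2e (n = %d)%s\n",
    nrow(x$map), x$calibration$d_star, x$calibration$mean_ref_sif,
    x$calibration$n_ref,
    if (x$calibration$poor_calibration) " [poor calibration]" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-pixel retrieval map
#'
#' @param x An `sfm_retrieval` object.
#' @param ... Unused.
#' @return The per-pixel map tibble.
#' @exportS3Method generics::tidy
tidy.sfm_retrieval <- function(x, ...) x$map

#' One-row retrieval summary
#'
#' @param x An `sfm_retrieval` object.
#' @param ... Unused.
#' @return A one-row tibble: calibrated distance, mean reference SIF and
#'   reference count, pixel counts by outcome, and the median fit RMS.
#' @exportS3Method generics::glance
glance.sfm_retrieval <- function(x, ...) {
  tibble::tibble(
    d_star = x$calibration$d_star,
    mean_ref_sif = x$calibration$mean_ref_sif,
    n_ref = x$calibration$n_ref,
    poor_calibration = x$calibration$poor_calibration,
    n_converged = sum(x$map$flag != "failed"),
    n_failed = sum(x$map$flag == "failed"),
    median_rms = stats::median(x$map$rms, na.rm = TRUE)
  )
}
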