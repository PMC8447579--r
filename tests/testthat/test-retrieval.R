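test_that("reference selection finds exactly the bare-soil pixels", {
  sc <- tiny_scene()
  tr <- dplyr::filter(sc$truth, overpass == 2)
  refs <- select_reference_pixels(sc$radiance[[2]], sc$reflectance[[2]])
  expect_setequal(refs$pixel, tr$pixel[tr$soil])
})

test_that("the NDVI reference threshold is inclusive and emptiness errors", {
  # hand-built cube: three pixels with NDVI 0.05, 0.1 (exactly), 0.5
  wl <- default_reflectance_wavelength()
  # 0.6875/0.5625 give NDVI exactly 0.1 in floating point (0.125 / 1.25)
  nirv <- c(0.21, 0.6875, 0.6); redv <- c(0.19, 0.5625, 0.2)
  vals <- matrix(0.1, 3, length(wl))
  vals[, wl >= 795 & wl < 810] <- nirv
  vals[, wl >= 665 & wl < 680] <- redv
  cube <- spectral_cube(vals, wl, nx = 3, ny = 1)
  refs <- select_reference_pixels(cube, cube)
  expect_setequal(refs$pixel, c(1L, 2L))
  # all-vegetation cube: calibration impossible
  vals[, wl >= 665 & wl < 680] <- 0.03
  veg_cube <- spectral_cube(vals, wl, nx = 3, ny = 1)
  expect_error(select_reference_pixels(veg_cube, veg_cube),
               "calibration is impossible")
})

test_that("noise-free pixel fits recover injected SIF within tight bounds", {
  inj <- c(0, 2)
  tr <- manual_truth(sif_canopy = inj)
  atm <- atmospheric_table()
  rad <- to_at_sensor(truth_to_reflectance(tr), tr, atm)
  for (i in seq_along(inj)) {
    fit <- fit_pixel(rad$values[i, ], rad$wavelength, atm, d = 1)
    expect_identical(fit$flag, "converged")
    expect_lt(abs(fit$sif760 - inj[i]), if (inj[i] == 0) 0.01 else 0.02)
  }
})

test_that("retrieved SIF is linear in injected SIF with unit slope", {
  inj <- seq(0, 4, length.out = 9)
  tr <- manual_truth(sif_canopy = inj)
  atm <- atmospheric_table()
  rad <- to_at_sensor(truth_to_reflectance(tr), tr, atm)
  cfg <- retrieval_config()
  ret <- vapply(seq_along(inj), function(i) {
    fit_pixel(rad$values[i, ], rad$wavelength, atm, d = 1, cfg)$sif760
  }, numeric(1))
  slope <- stats::coef(stats::lm(ret ~ inj))[["inj"]]
  expect_equal(slope, 1, tolerance = 0.02)
})

test_that("distance calibration lands within one grid step of the truth", {
  sc <- cached_scene("offgrid", nx = 24, ny = 24, seed = 303, distance = 1.02)
  cal_ret <- retrieve_scene(sc$radiance[[3]], sc$reflectance[[3]], sc$atm,
                            retrieval_config(),
                            e_scale = sc$overpasses$ppfd[3] / 2000)
  step <- diff(retrieval_config()$distance_grid[1:2])
  expect_lt(abs(cal_ret$calibration$d_star - 1.02), step)
})

test_that("mean reference SIF is monotone in distance and vanishes at the truth", {
  sc <- tiny_scene()
  refs <- select_reference_pixels(sc$radiance[[3]], sc$reflectance[[3]])
  cfg <- retrieval_config(distance_grid = seq(0.8, 1.2, by = 0.05))
  cal <- calibrate_effective_distance(sc$radiance[[3]], refs, sc$atm, cfg,
                                      e_scale = sc$overpasses$ppfd[3] / 2000)
  expect_lt(abs(cal$mean_ref_sif), 0.01)   # noise-free calibration objective
  expect_false(cal$poor_calibration)
  prof <- cal$profile
  # systematic opposite-sign soil SIF for deliberately wrong distances
  expect_lt(prof$mean_sif[prof$d == 0.8], -0.1)
  expect_gt(prof$mean_sif[prof$d == 1.2], 0.1)
  expect_true(all(diff(prof$mean_sif) > 0))
  # sign change brackets the true distance
  expect_identical(findInterval(0, range(prof$mean_sif)), 1L)
})

test_that("scene retrieval recovers truth and books reference pixels", {
  sc <- tiny_scene()
  op <- 4
  ret <- retrieve_scene(sc$radiance[[op]], sc$reflectance[[op]], sc$atm,
                        retrieval_config(),
                        e_scale = sc$overpasses$ppfd[op] / 2000)
  tr <- dplyr::filter(sc$truth, overpass == op)
  m <- tidy(ret)
  hi <- tr$sif_canopy > 0.5
  expect_lt(max(abs(m$sif760[hi] - tr$sif_canopy[hi]) / tr$sif_canopy[hi]),
            0.01)
  expect_setequal(m$pixel[m$flag == "reference"], tr$pixel[tr$soil])
  g <- glance(ret)
  expect_identical(g$n_failed, 0L)
  expect_s3_class(g, "tbl_df")
})

test_that("without the absorption band the fit is degenerate and flagged", {
  atm <- atmospheric_table()
  atm$k_o2[] <- 0                      # transmittance identically 1
  tr <- manual_truth(sif_canopy = c(1, 2))
  rad <- to_at_sensor(truth_to_reflectance(tr), tr, atm)
  ret <- suppressWarnings(
    fit_pixel(rad$values[1, ], rad$wavelength, atm, d = 1))
  expect_identical(ret$flag, "failed")
  expect_true(is.na(ret$sif760))
})

test_that("noisy retrieval is unbiased over many pixels", {
  n <- 1000
  tr <- manual_truth(sif_canopy = rep(2, n))
  atm <- atmospheric_table()
  rad <- to_at_sensor(truth_to_reflectance(tr), tr, atm, snr = 250, seed = 21)
  refl <- truth_to_reflectance(tr)
  cfg <- retrieval_config()
  inw <- rad$wavelength >= cfg$window[1] & rad$wavelength <= cfg$window[2]
  design <- sifdown:::sfm_design(atm, 1, cfg, rad$wavelength[inw])
  fits <- sifdown:::fit_sfm_block(rad$values[, inw], design, cfg$a_floor)
  err <- fits$sif760 - 2
  se <- stats::sd(err) / sqrt(n)
  expect_lt(abs(mean(err)), 2 * se + 1e-3)
})
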