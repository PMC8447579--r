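test_that("FCVI subtracts the visible mean from the 770 nm reflectance", {
  wl <- default_reflectance_wavelength()
  flat <- spectral_cube(matrix(0.25, 2, length(wl)), wl, nx = 2, ny = 1)
  expect_equal(fcvi(flat), c(0, 0))
  vals <- matrix(0.05, 1, length(wl))
  vals[wl >= 750] <- 0.50
  cube <- spectral_cube(vals, wl, nx = 1, ny = 1)
  expect_equal(fcvi(cube), 0.45)
  # fcvi never exceeds the 770 nm reflectance
  refl <- tiny_scene()$reflectance[[2]]
  expect_true(all(fcvi(refl) <= band_at(refl, 770)))
  # a cube without a band near 770 nm errors
  wl_no <- wl[wl < 760 | wl > 781]
  cube_no <- spectral_cube(matrix(0.2, 1, length(wl_no)), wl_no, nx = 1, ny = 1)
  expect_error(fcvi(cube_no), "770")
})

test_that("escape fraction masks rather than clips, with one reason each", {
  ef <- escape_fraction(
    fcvi = c(0.45, 0.5, 0.17, 0.6, NA, 0.4),
    fapar_chl = c(0.75, 0.5, 0.75, 0.5, 0.5, 0)
  )
  expect_equal(ef$fesc[1], 0.6)
  expect_equal(ef$fesc[2], 1)            # upper boundary is valid
  expect_true(ef$valid[2])
  expect_identical(ef$flag[3], "low_fcvi")    # 0.17 < 0.18 threshold
  expect_identical(ef$flag[4], "fesc_gt_1")   # 1.2 masked, not clipped
  expect_true(is.na(ef$fesc[4]))
  expect_identical(ef$flag[5], "missing")
  expect_identical(ef$flag[6], "nonpos_fapar")
  expect_true(all(ef$fesc[ef$valid] > 0 & ef$fesc[ef$valid] <= 1))
  # exactly one reason code per invalid pixel, "ok" elsewhere
  expect_identical(sum(ef$flag == "ok"), sum(ef$valid))
  # the threshold itself is included
  expect_true(escape_fraction(0.18, 0.9)$valid)
  expect_error(escape_fraction(c(0.4, 0.5), 0.5), "not aligned")
})

test_that("leaf SIF applies the pi over f_esc factor on valid pixels", {
  expect_equal(sif_leaf(1, 1), pi)
  expect_equal(sif_leaf(1, 0.5), 2 * pi)
  expect_true(is.na(sif_leaf(1, NA, valid = FALSE)))
  expect_error(sif_leaf(1, 0, valid = TRUE), "mask contract")
  # monotone decreasing in fesc
  fe <- seq(0.2, 1, by = 0.1)
  expect_true(all(diff(sif_leaf(1, fe)) < 0))
})

test_that("downscale then upscale returns canopy SIF exactly", {
  sc <- tiny_scene()
  tr <- dplyr::filter(sc$truth, overpass == 3)
  refl <- sc$reflectance[[3]]
  d <- tibble::tibble(
    fcvi = fcvi(refl),
    fapar_chl = vegetation_indices(refl)$fapar_chl,
    sif_canopy = tr$sif_canopy
  ) |> downscale_sif()
  v <- d$valid
  expect_equal(d$fesc[v] * d$sif_leaf[v] / pi, d$sif_canopy[v],
               tolerance = 1e-14)
  # and the leaf map matches the generator truth
  expect_lt(max(abs(d$sif_leaf[v] - tr$sif_leaf[v]) / tr$sif_leaf[v]), 1e-10)
})

test_that("full-pipeline escape-fraction recovery stays within 5% at SNR 250", {
  run <- run_pipeline(run_config(nx = 32, ny = 32, seed = 77, snr = 250))
  j <- dplyr::inner_join(
    run$pixels,
    dplyr::select(run$scene$truth, overpass, pixel,
                  fesc_true = fesc, soil),
    by = c("overpass", "pixel")
  )
  v <- j$valid & !j$soil
  rel <- abs(j$fesc[v] - j$fesc_true[v]) / j$fesc_true[v]
  expect_lt(stats::median(rel), 0.05)
})
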