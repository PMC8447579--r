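test_that("band means follow the half-open window convention", {
  wl <- c(660, 670, 680, 700)
  cube <- spectral_cube(matrix(c(0.2, 0.4, 0.6, 0.8), 1), wl, nx = 1, ny = 1)
  expect_equal(band_mean(cube, c(665, 675)), 0.4)        # single band
  expect_equal(band_mean(cube, c(660, 690)), mean(c(0.2, 0.4, 0.6)))
  expect_equal(band_mean(cube, c(660, 700.0001)), 0.5)   # includes 700
  const <- spectral_cube(matrix(0.3, 2, 4), wl, nx = 2, ny = 1)
  expect_equal(band_mean(const, c(660, 700)), c(0.3, 0.3))
  expect_error(band_mean(cube, c(705, 710)), "\\[705, 710\\)")
})

test_that("WDRVI matches its closed form and reduces to NDVI at alpha 1", {
  expect_equal(wdrvi(0.5, 0.05), 0)
  expect_equal(wdrvi(0.2, 0.2), (0.1 - 1) / (0.1 + 1))   # -0.818181...
  expect_equal(wdrvi(0.2, 0.2), -0.8181818, tolerance = 1e-7)
  nir <- c(0.5, 0.42); red <- c(0.04, 0.3)
  expect_equal(wdrvi(nir, red, alpha = 1), ndvi(nir, red))
  expect_true(is.na(wdrvi(0, 0)))
  expect_error(wdrvi(-0.1, 0.2), "non-negative")
  # antisymmetry under swapping alpha*nir and red
  a <- 0.1; nirs <- runif(20, 0.1, 0.9); reds <- runif(20, 0.01, 0.4)
  expect_equal(wdrvi(nirs, reds, a), -wdrvi(reds / a, a * nirs, a))
  expect_true(all(abs(wdrvi(nirs, reds)) <= 1))
})

test_that("fAPAR_green mapping is linear, clamped, and monotone", {
  expect_equal(as.numeric(fapar_green(0)), 0.726)
  expect_equal(as.numeric(fapar_green(-1)), 0.21)
  g <- fapar_green(0.6)                                  # 1.0356 -> clamped
  expect_equal(as.numeric(g), 1)
  expect_identical(attr(g, "n_clamped"), 1L)
  w <- seq(-1, 1, by = 0.05)
  f <- as.numeric(fapar_green(w))
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(fapar_green(1.5), "\\[-1, 1\\]")
})

test_that("fAPAR_chl scales fAPAR_green by k", {
  expect_equal(fapar_chl(1), 0.79)
  expect_equal(fapar_chl(0), 0)
  expect_equal(fapar_chl(0.726), 0.57354)
  expect_error(fapar_chl(0.5, k = 0), "\\(0, 1\\]")
  expect_error(fapar_chl(0.5, k = 1.2), "\\(0, 1\\]")
  # never exceeds fapar_green
  fg <- runif(50)
  expect_true(all(fapar_chl(fg) <= fg))
})

test_that("APAR_chl is the product of fAPAR_chl and PAR", {
  expect_equal(apar_chl(0.5, 2e5), 1e5)
  expect_equal(apar_chl(c(0.2, 0.7), 0), c(0, 0))
  expect_error(apar_chl(0.5, -1), "non-negative")
  # consistency with the generator truth
  sc <- tiny_scene()
  tr <- dplyr::filter(sc$truth, overpass == 5)
  vi <- vegetation_indices(sc$reflectance[[5]], par_mw = tr$par_mw[1])
  veg <- !tr$soil
  truth_apar <- tr$fapar_chl[veg] * tr$par_mw[veg]
  expect_lt(max(abs(vi$apar_chl[veg] - truth_apar) / truth_apar), 1e-10)
})
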