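test_that("consistent-mode reflectance inverts to the truth exactly", {
  sc <- tiny_scene()
  for (op in c(1L, 4L)) {
    tr <- dplyr::filter(sc$truth, overpass == op)
    refl <- sc$reflectance[[op]]
    veg <- !tr$soil
    f <- fcvi(refl)
    expect_lt(max(abs(f[veg] - tr$fapar_chl[veg] * tr$fesc[veg]) /
                    (tr$fapar_chl[veg] * tr$fesc[veg])), 1e-10)
    vi <- vegetation_indices(refl)
    expect_lt(max(abs(vi$fapar_green[veg] - tr$fapar_green[veg])), 1e-10)
    # full downscale chain recovers the escape fraction
    ef <- escape_fraction(f, vi$fapar_chl)
    expect_lt(max(abs(ef$fesc[veg] - tr$fesc[veg]) / tr$fesc[veg],
                  na.rm = TRUE), 1e-10)
  }
})

test_that("bare-soil pixels have a flat spectrum with zero FCVI and NDVI", {
  sc <- tiny_scene()
  tr <- dplyr::filter(sc$truth, overpass == 1)
  refl <- sc$reflectance[[1]]
  soil <- tr$soil
  expect_true(any(soil))
  expect_equal(fcvi(refl)[soil], rep(0, sum(soil)))
  vi <- vegetation_indices(refl)
  expect_equal(vi$ndvi[soil], rep(0, sum(soil)))
})

test_that("pixels outside the invertible fAPAR range are flagged, not altered", {
  tr <- manual_truth(sif_canopy = c(1, 1), fapar_chl = c(0.6, 0.18),
                     fesc = 0.6)
  # fapar_green = 0.18 / 0.79 = 0.228 implies WDRVI below the solvable range
  refl <- truth_to_reflectance(tr)
  expect_identical(attr(refl, "flagged"), 2L)
  # flagged pixel got the fallback soil spectrum, not a distorted solution
  expect_equal(stats::sd(refl$values[2, ]), 0)
})

test_that("toy radiative-transfer mode recovers the escape fraction approximately", {
  sc <- cached_scene("toy", nx = 100, ny = 100, seed = 606, mode = "toy_rt")
  tr <- dplyr::filter(sc$truth, overpass == 3)
  refl <- sc$reflectance[[3]]
  vi <- vegetation_indices(refl)
  ef <- escape_fraction(fcvi(refl), vi$fapar_chl)
  dense <- !tr$soil & tr$fapar_green > 0.8 & ef$valid
  expect_gt(sum(dense), 1000)
  rel <- abs(ef$fesc[dense] - tr$fesc[dense]) / tr$fesc[dense]
  expect_lt(stats::median(rel), 0.15)
})

test_that("reflectance cubes are smooth and within physical bounds", {
  refl <- tiny_scene()$reflectance[[1]]
  expect_true(all(refl$values >= 0 & refl$values <= 1))
  # no jumps larger than the red-edge slope allows between adjacent bands
  expect_lt(max(abs(diff(t(refl$values)))), 0.06)
})
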