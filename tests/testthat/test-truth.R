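truth_inputs <- function(times = default_overpass_times()) {
  grid_times <- sort(unique(round(c(seq(4, 21, by = 0.05), times), 6)))
  diurnal_par(solar_geometry(grid_times), par_max = 438)
}

test_that("a fixed seed gives bit-identical truth", {
  par <- truth_inputs()
  lay <- default_field_layout(16, 16)
  t1 <- generate_truth(default_archetypes(), lay, 16, 16,
                       default_overpass_times(), par, seed = 9)
  t2 <- generate_truth(default_archetypes(), lay, 16, 16,
                       default_overpass_times(), par, seed = 9)
  expect_identical(t1, t2)
  t3 <- generate_truth(default_archetypes(), lay, 16, 16,
                       default_overpass_times(), par, seed = 10)
  expect_false(identical(t1$fapar_chl, t3$fapar_chl))
})

test_that("truth satisfies its defining identities exactly", {
  tr <- tiny_scene()$truth
  veg <- !tr$soil
  expect_identical(tr$sif_canopy[veg],
                   tr$fesc[veg] * tr$sif_leaf[veg] / pi)
  expect_identical(tr$sif_leaf[veg],
                   tr$eps_true[veg] * tr$fapar_chl[veg] * tr$par_mw[veg])
  expect_true(all(tr$fapar_chl >= 0 & tr$fapar_chl <= tr$fapar_green))
  expect_true(all(tr$fapar_green <= 1))
  expect_true(all(tr$fesc[veg] > 0 & tr$fesc[veg] <= 1))
  # soil pixels: zero absorption and emission, undefined escape fraction
  expect_true(all(tr$fapar_chl[!veg] == 0))
  expect_true(all(tr$sif_canopy[!veg] == 0))
  expect_true(all(is.na(tr$fesc[!veg])))
})

test_that("diurnal escape-fraction dynamics follow the archetype shapes", {
  tr <- tiny_scene()$truth
  veg <- dplyr::filter(tr, !soil)
  wide <- veg |>
    dplyr::select(dplyr::all_of(c("pixel", "crop", "overpass", "fesc"))) |>
    tidyr::pivot_wider(names_from = "overpass", values_from = "fesc")
  wheat <- dplyr::filter(wide, crop == "wheat_like")
  for (op in as.character(2:6)) expect_identical(wheat[[op]], wheat[["1"]])
  beet <- dplyr::filter(wide, crop == "sugarbeet_like")
  ops <- as.matrix(beet[, as.character(1:6)])
  expect_true(all(diff(t(ops)) >= 0))              # monotone rise
  expect_equal(ops[, 6], ops[, 5], tolerance = 1e-12) # plateau after 14:40
  amp <- default_archetypes()$fesc_diurnal_amplitude[1]
  expect_equal(unname(ops[, 6] - ops[, 1]), rep(amp, nrow(ops)),
               tolerance = 1e-6)
})

test_that("NPQ depression produces the hysteresis; removing it closes the loop", {
  # two times symmetric about solar noon have identical PAR
  times <- c(11.5, 15.5)
  par <- truth_inputs(times)
  lay <- default_field_layout(12, 12)
  base <- list(archetypes = default_archetypes(), layout = lay,
               nx = 12, ny = 12, times = times, par = par, seed = 4)
  t_npq <- do.call(generate_truth, c(base, d_npq = 0.3))
  t_flat <- do.call(generate_truth, c(base, d_npq = 0))
  p1 <- dplyr::filter(t_npq, overpass == 1, !soil)
  p2 <- dplyr::filter(t_npq, overpass == 2, !soil)
  expect_equal(p1$par_mw, p2$par_mw)               # matched driver
  expect_true(all(p2$eps_true < p1$eps_true))      # afternoon depressed
  f1 <- dplyr::filter(t_flat, overpass == 1, !soil)
  f2 <- dplyr::filter(t_flat, overpass == 2, !soil)
  expect_equal(f2$eps_true, f1$eps_true, tolerance = 1e-12)
})

test_that("truth generation validates its inputs", {
  par <- truth_inputs()
  expect_error(
    generate_truth(default_archetypes(), default_field_layout(16, 16),
                   16, 16, times = c(12.5, 23.9), par, seed = 1),
    "missing from the PAR series"
  )
  bad_layout <- field_layout("A", "unknown_crop",
                             list(cbind(c(2, 10, 10, 2), c(2, 2, 10, 10))))
  expect_error(
    generate_truth(default_archetypes(), bad_layout, 16, 16,
                   default_overpass_times(), par, seed = 1),
    "without an archetype"
  )
})
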