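square_layout <- function() {
  field_layout(c("A", "B"), c("wheat_like", "wheat_like"),
               list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)),
                    cbind(c(4, 8, 8, 4), c(0, 0, 4, 4))))
}

test_that("field percentiles match brute-force order statistics", {
  px <- grid_pixels(8, 4) |>
    assign_fields(square_layout()) |>
    dplyr::mutate(overpass = 1L, time = 12,
                  v = rep(c(1, 2, 3, 4, 5), length.out = 32),
                  w = 7)
  fs <- field_stats(px, vars = c("v", "w"))
  a_v <- dplyr::filter(fs, field == "A", variable == "v")
  vals <- px$v[px$field == "A"]
  expect_equal(a_v$p0, min(vals))
  expect_equal(a_v$p100, max(vals))
  expect_equal(a_v$p50, unname(stats::quantile(vals, 0.5, type = 7)))
  expect_equal(a_v$p25, unname(stats::quantile(vals, 0.25, type = 7)))
  expect_equal(a_v$mean, mean(vals))
  expect_equal(a_v$n, length(vals))
  # constant field: all percentiles collapse
  a_w <- dplyr::filter(fs, field == "A", variable == "w")
  expect_true(all(c(a_w$p0, a_w$p25, a_w$p50, a_w$p75, a_w$p100) == 7))
  # explicit five-value check
  ex <- tibble::tibble(field = "F", crop = "c", overpass = 1L, time = 1,
                       v = c(1, 2, 3, 4, 5))
  s5 <- field_stats(ex, vars = "v")
  expect_equal(c(s5$p0, s5$p50, s5$p100), c(1, 3, 5))
  # ordering invariant
  expect_true(all(fs$p0 <= fs$p25 & fs$p25 <= fs$p50 &
                    fs$p50 <= fs$p75 & fs$p75 <= fs$p100))
})

test_that("the validity mask controls the pixel count, empty fields warn", {
  px <- grid_pixels(8, 4) |>
    assign_fields(square_layout()) |>
    dplyr::mutate(overpass = 1L, time = 12, v = 1,
                  ok = x < 4 & dplyr::row_number() %% 2 == 0)
  expect_warning(fs <- field_stats(px, vars = "v", valid = "ok"), "omitted")
  expect_identical(fs$n, sum(px$ok[px$field == "A"]))
  expect_false("B" %in% fs$field)
})

test_that("canopy-leaf correlation equals the direct oracle per field", {
  sc <- tiny_scene()
  tr <- dplyr::filter(sc$truth, overpass == 2) |>
    dplyr::mutate(valid = !soil)
  cors <- canopy_leaf_correlation(tr)
  for (f in unique(cors$field)) {
    sub <- dplyr::filter(tr, field == f, valid)
    expect_equal(cors$r[cors$field == f],
                 stats::cor(sub$sif_canopy, sub$sif_leaf))
  }
  # heterogeneous escape fraction keeps r strictly below 1
  orch <- dplyr::filter(cors, crop == "orchard_like")
  expect_true(all(orch$r < 1))
})

test_that("correlation degenerates gracefully", {
  base <- tibble::tibble(field = "A", crop = "c", overpass = 1L, time = 1)
  # affine map (constant fesc): r is exactly 1
  d1 <- dplyr::mutate(base[rep(1, 10), ],
                      sif_canopy = 1:10, sif_leaf = pi * (1:10) / 0.55)
  expect_equal(canopy_leaf_correlation(d1)$r, 1)
  d2 <- dplyr::mutate(base[rep(1, 10), ],
                      sif_canopy = 1:10, sif_leaf = -(1:10))
  expect_equal(canopy_leaf_correlation(d2)$r, -1)
  d3 <- dplyr::mutate(base[rep(1, 10), ], sif_canopy = 5, sif_leaf = 1:10)
  out <- canopy_leaf_correlation(d3)
  expect_true(is.na(out$r))
  expect_identical(out$flag, "zero_variance")
  d4 <- dplyr::mutate(base[rep(1, 2), ], sif_canopy = 1:2, sif_leaf = 1:2)
  expect_identical(canopy_leaf_correlation(d4)$flag, "n_lt_3")
})

test_that("crop-level aggregation averages field correlations", {
  cors <- tibble::tibble(
    field = c("A", "B", "C"), crop = c("x", "x", "y"),
    overpass = 1L, time = 1, n = 10, flag = "ok", r = c(0.9, 0.7, 0.5)
  )
  agg <- correlation_by_crop(cors)
  expect_equal(agg$r_mean[agg$crop == "x"], 0.8)
  expect_equal(agg$r_sd[agg$crop == "x"], stats::sd(c(0.9, 0.7)))
  expect_identical(agg$n_fields, c(2L, 1L))
})

test_that("hysteresis orders records in time and needs two overpasses", {
  tr <- tiny_scene()$truth |>
    dplyr::mutate(valid = !soil, apar_chl = fapar_chl * par_mw)
  h <- hysteresis(tr, eps = "eps_true", driver = "apar_chl")
  expect_s3_class(h, "sif_hysteresis")
  expect_true(all(tapply(h$time, h$crop, function(t) all(diff(t) > 0))))
  expect_error(hysteresis(dplyr::filter(tr, overpass == 1),
                          eps = "eps_true", driver = "apar_chl"),
               "at least two")
})

test_that("NPQ forcing makes the afternoon branch fall below the morning branch", {
  # overpasses 2 (11:15) and 5 (15:50) have nearly matched PAR
  tr <- tiny_scene()$truth |> dplyr::mutate(valid = !soil)
  h <- hysteresis(tr, eps = "eps_true", driver = "par_mw")
  for (cr in unique(h$crop)) {
    hh <- dplyr::filter(h, crop == cr)
    expect_lt(abs(hh$driver_mean[5] - hh$driver_mean[2]) / hh$driver_mean[2],
              0.05)
    expect_lt(hh$eps_mean[5], hh$eps_mean[2])
  }
})
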