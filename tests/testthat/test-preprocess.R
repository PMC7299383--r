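make_flagged_cube <- function(flags_vec) {
  n <- length(flags_vec)
  tibble::tibble(
    pixel = 1L, row = 1L, col = 1L, lon = 80, lat = 40,
    year = 1982, step = seq_len(n), month = ceiling(seq_len(n) / 2),
    value = seq_len(n) / 10, flag = flags_vec, valid = TRUE
  )
}

test_that("quality masking keeps exactly the reliable-flag cells", {
  cube <- make_flagged_cube(c(1L, 2L, 4L, 1L, 4L, 5L))
  out <- apply_quality_mask(cube, keep_flags = c(1, 2, 3, 5))
  expect_identical(out$valid, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(out$value, cube$value) # values never altered
  # all kept / none kept
  expect_true(all(apply_quality_mask(cube, keep_flags = c(1, 2, 4, 5))$valid))
  expect_false(any(apply_quality_mask(cube, keep_flags = integer(0))$valid))
  # idempotent
  expect_identical(apply_quality_mask(out, keep_flags = c(1, 2, 3, 5)), out)
})

test_that("quality masking rejects a misaligned external flag layer", {
  cube <- make_flagged_cube(rep(1L, 6))
  flags <- tibble::tibble(pixel = 1L, year = 1982, step = 1:3, flag = 1L)
  expect_error(apply_quality_mask(cube, flags), "misaligned")
})

test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  t <- 1:31
  lin <- 2 + 0.3 * t
  expect_equal(savgol_smooth(lin, 7, 1), lin, tolerance = 1e-10)
  expect_equal(savgol_smooth(lin, 7, 2), lin, tolerance = 1e-10)
  cub <- 1 - 0.2 * t + 0.05 * t^2 - 0.001 * t^3
  expect_equal(savgol_smooth(cub, 7, 3), cub, tolerance = 1e-8)
  # but a window-2 fit does not reproduce a cubic
  expect_gt(max(abs(savgol_smooth(cub, 7, 2) - cub)), 1e-6)
})

test_that("interior smoothing equals convolution with normal-equation
           coefficients", {
  set.seed(3)
  x <- rnorm(41)
  for (po in c(2, 3)) {
    sm <- savgol_smooth(x, 7, po)
    co <- sg_coefficients(7, po)
    manual <- vapply(4:38, function(i) sum(co * x[(i - 3):(i + 3)]),
      numeric(1)
    )
    expect_equal(sm[4:38], manual, tolerance = 1e-10)
  }
  expect_error(savgol_smooth(x, 6, 2), "odd")
  expect_error(savgol_smooth(x, 7, 7), "polyorder")
})

test_that("short gaps are interpolated, long gaps stay invalid", {
  x <- as.numeric(1:31)
  x[10:12] <- NA # gap of 3: filled
  sm <- savgol_smooth(x, 7, 2, max_gap = 3)
  expect_equal(sm, as.numeric(1:31), tolerance = 1e-10)
  x[20:24] <- NA # gap of 5: kept missing
  sm2 <- savgol_smooth(x, 7, 2, max_gap = 3)
  expect_true(all(is.na(sm2[20:24])))
})

test_that("smoothing preserves the mean of a periodic series over whole
           periods", {
  t <- 0:(24 * 4 - 1)
  x <- 0.3 + 0.1 * sin(2 * pi * t / 24)
  sm <- savgol_smooth(x, 7, 2)
  expect_equal(mean(sm[13:(13 + 23)]), mean(x[13:(13 + 23)]),
    tolerance = 1e-3
  )
})

test_that("barren filter removes exactly the sub-threshold pixels,
           strictly below 0.05", {
  m <- cbind(
    rep(0.04, 10), rep(0.05, 10), rep(0.3, 10),
    c(rep(0.04, 9), 0.06)
  )
  cube <- annual_cube_from_matrix(m)
  out <- mask_barren(cube)
  expect_equal(attr(out, "n_barren"), 2) # pixels 1 and 4
  expect_false(any(out$valid[out$pixel == 1]))
  expect_true(all(out$valid[out$pixel == 2])) # 0.05 retained: strict <
  expect_true(all(out$valid[out$pixel == 3]))
  expect_false(any(out$valid[out$pixel == 4])) # mean 0.042 < 0.05
  # idempotent
  again <- mask_barren(out)
  expect_identical(again$valid, out$valid)
})

test_that("GSVI compositing averages exactly the in-window observations", {
  # ten semimonthly May-Sep slots valued 0.1 .. 1.0 -> mean 0.55
  cube <- tibble::tibble(
    pixel = 1L, row = 1L, col = 1L, lon = 80, lat = 40,
    year = 1982, step = 1:24, month = ceiling((1:24) / 2),
    value = 0, valid = TRUE
  )
  gs_rows <- cube$month %in% 5:9
  cube$value[gs_rows] <- seq(0.1, 1.0, by = 0.1)
  g <- composite_gsvi(cube)
  expect_equal(g$value, 0.55)
  expect_true(g$valid)
  # perturbing off-season values never changes GSVI
  cube2 <- cube
  cube2$value[!gs_rows] <- rnorm(sum(!gs_rows), 5, 10)
  expect_equal(composite_gsvi(cube2)$value, 0.55)
  # constant window
  cube$value[gs_rows] <- 0.3
  expect_equal(composite_gsvi(cube)$value, 0.3)
})

test_that("years below the minimum observation count become invalid", {
  cube <- tibble::tibble(
    pixel = 1L, row = 1L, col = 1L, lon = 80, lat = 40,
    year = 1982, step = 1:24, month = ceiling((1:24) / 2),
    value = 0.3, valid = TRUE
  )
  cube$valid[cube$month %in% 5:9][1:4] <- FALSE # 6 valid < 7
  expect_false(composite_gsvi(cube, min_obs = 7)$valid)
  expect_true(composite_gsvi(cube, min_obs = 6)$valid)
})

test_that("nearest-neighbour regridding copies the covering coarse value", {
  ny <- 3
  coarse <- monthly_cube(4, ny, function(yi, m) 0)
  # distinct value per coarse pixel
  coarse$value <- coarse$pixel * 10
  fine_grid <- make_grid(8, 8,
    lon0 = min(coarse$lon) - 0.05,
    lat0 = max(coarse$lat) + 0.05, res = 0.05
  )
  out <- regrid_nearest(coarse, fine_grid)
  expect_equal(nrow(out), 64 * ny * 12)
  # brute-force check on a sample of fine pixels
  src <- dplyr::distinct(coarse[, c("pixel", "lon", "lat")])
  for (p in c(1, 13, 40, 64)) {
    tgt <- fine_grid[fine_grid$pixel == p, ]
    d <- (src$lon - tgt$lon)^2 + (src$lat - tgt$lat)^2
    expect_equal(
      unique(out$value[out$pixel == p]),
      src$pixel[which.min(d)] * 10
    )
  }
  # identity on identical grids
  idg <- dplyr::distinct(coarse[, c("pixel", "row", "col", "lon", "lat")])
  same <- regrid_nearest(coarse, idg)
  expect_equal(
    dplyr::arrange(same, pixel, year, month)$value,
    dplyr::arrange(coarse, pixel, year, month)$value
  )
  far <- make_grid(2, 2, lon0 = 150, lat0 = -40)
  expect_error(regrid_nearest(coarse, far), "disjoint")
})

test_that("monthly aggregation sums or averages sub-monthly records", {
  # 8 three-hourly steps/day x 30 days at constant 10
  cube <- tibble::tibble(
    pixel = 1L, row = 1L, col = 1L, lon = 80, lat = 40,
    year = 1982, month = 6L, value = 10, valid = TRUE,
    .rows = 8 * 30
  )
  expect_equal(aggregate_monthly(cube, "sum")$value, 2400)
  expect_equal(aggregate_monthly(cube, "mean")$value, 10)
  cube$valid <- FALSE
  expect_false(aggregate_monthly(cube, "mean")$valid)
  expect_error(aggregate_monthly(cube, "max"), "arg")
})
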