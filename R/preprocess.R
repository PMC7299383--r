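# Quality masking, smoothing, growing-season compositing, regridding.

#' Define the seasonal windows of the analysis year
#'
#' The year is split into a preseason (Jan-Apr), growing season (May-Sep) and
#' postseason (Oct-Dec); all windows lie in the same calendar year and must
#' be disjoint.
#'
#' @param preseason,growing,postseason Integer month sets.
#' @return A list of class `season_windows`.
#' @examples
#' season_windows()
#' @export
season_windows <- function(preseason = 1:4, growing = 5:9,
                           postseason = 10:12) {
  all <- c(preseason, growing, postseason)
  if (anyDuplicated(all) || any(all < 1 | all > 12)) {
    rlang::abort("windows must be disjoint month sets within one year")
  }
  structure(
    list(
      preseason = as.integer(preseason),
      growing = as.integer(growing),
      postseason = as.integer(postseason)
    ),
    class = "season_windows"
  )
}

#' Invalidate observations with unreliable quality flags
#'
#' Cells whose quality flag is not in `keep_flags` are marked invalid; values
#' are never altered. The flag layer may live in the cube itself (a `flag`
#' column, as produced by [gen_ndvi_cube()]) or be passed as an aligned
#' tibble with `pixel`, time columns and a `flag` column.
#'
#' @param cube NDVI cube tibble.
#' @param flags Optional flag tibble aligned with `cube`; defaults to the
#'   cube's own `flag` column.
#' @param keep_flags Integer set of reliable flag values.
#' @return The cube with `valid` updated.
#' @export
apply_quality_mask <- function(cube, flags = NULL, keep_flags = c(1, 2, 3, 5)) {
  assert_cube(cube)
  if (is.null(flags)) {
    if (!"flag" %in% names(cube)) {
      rlang::abort("no `flag` column in cube and no `flags` tibble supplied")
    }
    fl <- cube$flag
  } else {
    key <- intersect(c("pixel", "year", "step", "month"), names(cube))
    key <- intersect(key, names(flags))
    j <- dplyr::left_join(
      dplyr::select(cube, dplyr::all_of(key)),
      dplyr::select(flags, dplyr::all_of(c(key, "flag"))),
      by = key
    )
    if (nrow(j) != nrow(cube) || anyNA(j$flag)) {
      rlang::abort(sprintf(
        "flag layer misaligned with cube: %d cube cells, %d joined",
        nrow(cube), sum(!is.na(j$flag))
      ))
    }
    fl <- j$flag
  }
  cube$valid <- cube$valid & fl %in% keep_flags
  cube
}

#' Savitzky-Golay smoothing of one pixel series
#'
#' Least-squares local-polynomial smoothing with an odd moving window
#' (default 7 points, the standard choice for semimonthly NDVI), delegating
#' to [signal::sgolayfilt()]. `NA` gaps up to `max_gap` consecutive points
#' are linearly interpolated before smoothing and returned as valid; longer
#' gaps stay `NA`.
#'
#' @param x Numeric series, possibly with `NA` gaps.
#' @param window Odd window length.
#' @param polyorder Polynomial order, < `window`. Default 2, standard for
#'   NDVI phenology smoothing.
#' @param max_gap Longest internal gap (in steps) that is interpolated.
#' @return Smoothed numeric series of equal length.
#' @examples
#' savgol_smooth(sin(seq(0, 6, 0.2)) + rnorm(31, 0, 0.05))
#' @export
savgol_smooth <- function(x, window = 7, polyorder = 2, max_gap = 3) {
  if (window %% 2 == 0) rlang::abort("`window` must be odd")
  if (polyorder >= window) rlang::abort("`polyorder` must be < `window`")
  filled <- zoo::na.approx(x, na.rm = FALSE, maxgap = max_gap)
  if (sum(!is.na(filled)) < window) {
    rlang::abort("series has fewer valid points than the smoothing window")
  }
  out <- rep(NA_real_, length(x))
  ok <- !is.na(filled)
  # smooth each contiguous valid run long enough for the window
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in seq_along(runs$values)) {
    if (runs$values[r] && runs$lengths[r] >= window) {
      seg <- starts[r]:ends[r]
      out[seg] <- signal::sgolayfilt(filled[seg], p = polyorder, n = window)
    }
  }
  out
}

#' Smooth every pixel series of a cube
#'
#' Applies [savgol_smooth()] per pixel along time; invalid cells enter as
#' gaps and come back valid only when the gap was short enough to
#' interpolate.
#'
#' @inheritParams apply_quality_mask
#' @inheritParams savgol_smooth
#' @return The cube with smoothed `value` and updated `valid`.
#' @export
smooth_cube <- function(cube, window = 7, polyorder = 2, max_gap = 3) {
  assert_cube(cube)
  ord <- order(cube$pixel, cube$year,
    if ("step" %in% names(cube)) cube$step else cube$month
  )
  cube <- cube[ord, ]
  x <- ifelse(cube$valid, cube$value, NA_real_)
  sm <- unlist(lapply(
    split(x, cube$pixel),
    function(v) savgol_smooth(v, window, polyorder, max_gap)
  ), use.names = FALSE)
  cube$value <- ifelse(is.na(sm), cube$value, sm)
  cube$valid <- !is.na(sm)
  cube
}

#' Remove barren pixels
#'
#' Pixels whose mean NDVI over all valid observations is strictly below
#' `threshold` (default 0.05) are invalidated for every time step — these are
#' barren surfaces where a vegetation trend is meaningless. The number of
#' removed pixels is attached as `attr(, "n_barren")`.
#'
#' @param cube NDVI cube tibble.
#' @param threshold Barren cutoff in NDVI units; comparison is strict (`<`).
#' @return The cube with barren pixels invalidated.
#' @export
mask_barren <- function(cube, threshold = 0.05) {
  assert_cube(cube)
  mu <- cube |>
    dplyr::filter(.data$valid) |>
    dplyr::summarise(mean_ndvi = mean(.data$value), .by = "pixel")
  barren <- mu$pixel[mu$mean_ndvi < threshold]
  cube$valid <- cube$valid & !(cube$pixel %in% barren)
  attr(cube, "n_barren") <- length(barren)
  cube
}

#' Composite a semimonthly cube into annual growing-season values
#'
#' GSVI for a pixel-year is the mean of its valid observations in the
#' growing-season months; years with fewer than `min_obs` valid in-window
#' observations (default 7 of the 10 semimonthly slots) are invalid.
#' Observations outside the window never influence the composite.
#'
#' @param cube Semimonthly NDVI cube (needs a `month` column).
#' @param windows A [season_windows()].
#' @param min_obs Minimum valid in-window observations per year.
#' @return Annual cube tibble: pixel, row, col, lon, lat, year, value, valid.
#' @export
composite_gsvi <- function(cube, windows = season_windows(), min_obs = 7) {
  assert_cube(cube, time_cols = c("year", "month"))
  if (length(windows$growing) == 0) rlang::abort("empty growing window")
  meta <- pixel_meta(cube)
  gs <- cube |>
    dplyr::filter(.data$month %in% windows$growing) |>
    dplyr::summarise(
      value = if (sum(.data$valid) > 0) {
        mean(.data$value[.data$valid])
      } else {
        NA_real_
      },
      n_obs = sum(.data$valid),
      .by = c("pixel", "year")
    ) |>
    dplyr::mutate(valid = .data$n_obs >= min_obs & is.finite(.data$value)) |>
    dplyr::select(!"n_obs")
  dplyr::left_join(meta, gs, by = "pixel") |>
    dplyr::arrange(.data$pixel, .data$year)
}

#' Nearest-neighbour regridding onto a target grid
#'
#' Each target pixel takes the value of the nearest source-cell center
#' (Euclidean distance in degrees); values are copied, never interpolated.
#'
#' @param coarse Source cube tibble (with `lon`, `lat`).
#' @param target_grid Target pixel table, e.g. from [make_grid()] or
#'   [pixel_meta] columns of a finer cube.
#' @return The source cube resampled onto the target grid (same time
#'   columns, target pixel identities).
#' @export
regrid_nearest <- function(coarse, target_grid) {
  assert_cube(coarse, time_cols = "year")
  tg <- dplyr::distinct(
    target_grid,
    dplyr::pick(dplyr::any_of(c("pixel", "row", "col", "lon", "lat")))
  )
  src <- pixel_meta(coarse)
  if (max(src$lon) < min(tg$lon) || min(src$lon) > max(tg$lon) ||
    max(src$lat) < min(tg$lat) || min(src$lat) > max(tg$lat)) {
    rlang::abort("source and target extents are disjoint")
  }
  # nearest source center per target center
  nn <- vapply(seq_len(nrow(tg)), function(i) {
    which.min((src$lon - tg$lon[i])^2 + (src$lat - tg$lat[i])^2)
  }, integer(1))
  map <- tibble::tibble(src_pixel = src$pixel[nn], tg[, ])
  tcols <- intersect(c("year", "month", "step", "value", "flag", "valid"),
    names(coarse))
  out <- dplyr::inner_join(
    dplyr::rename(map, pixel_new = "pixel"),
    dplyr::select(coarse, src_pixel = "pixel", dplyr::all_of(tcols)),
    by = "src_pixel", relationship = "many-to-many"
  )
  out$src_pixel <- NULL
  dplyr::rename(out, pixel = "pixel_new") |>
    dplyr::arrange(.data$pixel, .data$year)
}

#' Aggregate a sub-monthly cube to calendar months
#'
#' Temperature-like variables use the monthly mean, precipitation-like the
#' monthly sum. A month with no valid observations is invalid (a summed
#' month additionally requires all its observations valid, since a partial
#' sum is biased).
#'
#' @param cube Cube tibble with sub-monthly `value`s and a `month` column.
#' @param statistic `"mean"` or `"sum"`.
#' @return Monthly cube tibble.
#' @export
aggregate_monthly <- function(cube, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  assert_cube(cube, time_cols = c("year", "month"))
  meta <- pixel_meta(cube)
  agg <- cube |>
    dplyr::summarise(
      value = if (statistic == "mean") {
        if (sum(.data$valid) > 0) mean(.data$value[.data$valid]) else NA_real_
      } else {
        if (all(.data$valid)) sum(.data$value) else NA_real_
      },
      .by = c("pixel", "year", "month")
    ) |>
    dplyr::mutate(valid = is.finite(.data$value))
  dplyr::left_join(meta, agg, by = "pixel") |>
    dplyr::arrange(.data$pixel, .data$year, .data$month)
}
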