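# Tidy raster-cube containers.
#
# All cubes in this package are long tibbles, one row per pixel-time cell:
#   pixel, row, col, lon, lat  -- grid identity (north-up, row 1 = north edge)
#   year [, month | step]      -- calendar time
#   value                      -- NDVI, temperature, precipitation, z, ...
#   valid                      -- logical; invalid cells never enter statistics

#' Build a regular north-up pixel grid
#'
#' Returns one row per pixel with integer `row`/`col` indices and the
#' longitude/latitude of the pixel center. Row 1 is the northern edge.
#'
#' @param nrow,ncol Grid dimensions (pixels).
#' @param lon0,lat0 Longitude of the western edge and latitude of the northern
#'   edge, in degrees.
#' @param res Pixel size in degrees.
#' @return A tibble with columns `pixel`, `row`, `col`, `lon`, `lat`.
#' @examples
#' make_grid(2, 3)
#' @export
make_grid <- function(nrow, ncol, lon0 = 80, lat0 = 40, res = 0.1) {
  stopifnot(nrow >= 1, ncol >= 1, res > 0)
  g <- tidyr::expand_grid(row = seq_len(nrow), col = seq_len(ncol))
  tibble::tibble(
    pixel = seq_len(nrow * ncol),
    row = g$row,
    col = g$col,
    lon = lon0 + (g$col - 0.5) * res,
    lat = lat0 - (g$row - 0.5) * res
  )
}

#' @keywords internal
assert_cube <- function(cube, time_cols = "year") {
  need <- c("pixel", "value", "valid", time_cols)
  miss <- setdiff(need, names(cube))
  if (length(miss) > 0) {
    rlang::abort(paste0(
      "not a cube tibble: missing column(s) ",
      paste(miss, collapse = ", ")
    ))
  }
  invisible(cube)
}

# Annual cube -> time x pixel matrix (invalid cells NA), with pixel metadata
# kept as attributes. Internal workhorse for per-pixel statistics.
#' @keywords internal
annual_matrix <- function(cube) {
  assert_cube(cube)
  years <- sort(unique(cube$year))
  pix <- sort(unique(cube$pixel))
  m <- matrix(NA_real_, length(years), length(pix),
    dimnames = list(years, pix)
  )
  ok <- cube$valid & is.finite(cube$value)
  m[cbind(
    match(cube$year[ok], years),
    match(cube$pixel[ok], pix)
  )] <- cube$value[ok]
  attr(m, "years") <- years
  attr(m, "pixels") <- pix
  m
}

#' @keywords internal
pixel_meta <- function(cube) {
  cols <- intersect(c("pixel", "row", "col", "lon", "lat"), names(cube))
  dplyr::distinct(dplyr::select(cube, dplyr::all_of(cols)))
}
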