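# Standardized anomalies, Hovmoller sections, EOF decomposition.

#' Standardized anomaly (z-score) cube
#'
#' Per pixel, `(x_t - mean) / sd` over the pixel's own time series (sample
#' sd). Pixels with fewer than `min_years` valid years or zero variance are
#' invalidated.
#'
#' @param gsvi Annual cube tibble.
#' @param min_years Minimum valid years.
#' @return The cube with `value` replaced by z-scores.
#' @export
zscore_anomaly <- function(gsvi, min_years = 3) {
  assert_cube(gsvi)
  gsvi |>
    dplyr::mutate(
      .by = "pixel",
      n_ok = sum(.data$valid & is.finite(.data$value)),
      mu = mean(.data$value[.data$valid]),
      sg = stats::sd(.data$value[.data$valid]),
      value = dplyr::if_else(
        .data$valid & .data$n_ok >= min_years & .data$sg > 0,
        (.data$value - .data$mu) / .data$sg, NA_real_
      ),
      valid = .data$valid & .data$n_ok >= min_years &
        !is.na(.data$sg) & .data$sg > 0
    ) |>
    dplyr::select(!dplyr::all_of(c("n_ok", "mu", "sg")))
}

#' Hovmoller time-latitude / time-longitude section
#'
#' Averages a z-score cube over latitude (or longitude) bins for each year,
#' giving the classic time-versus-latitude section of anomaly evolution.
#' Pixels are assigned to half-open bins `[lo, hi)` by center coordinate.
#'
#' @param zcube Annual z-score cube (from [zscore_anomaly()]).
#' @param axis `"latitude"` or `"longitude"`.
#' @param bin_width Bin width in degrees (default 0.25).
#' @return A tibble of class `hovmoller`: `year`, `bin` (lower edge),
#'   `bin_mid`, `z` (mean over contributing pixels), `n_pixels`.
#' @export
hovmoller <- function(zcube, axis = c("latitude", "longitude"),
                      bin_width = 0.25) {
  axis <- match.arg(axis)
  if (bin_width <= 0) rlang::abort("`bin_width` must be positive")
  assert_cube(zcube)
  coord <- if (axis == "latitude") zcube$lat else zcube$lon
  lo <- floor(min(coord) / bin_width) * bin_width
  out <- zcube |>
    dplyr::mutate(bin = lo + bin_width *
      floor((coord - lo) / bin_width)) |>
    dplyr::filter(.data$valid & is.finite(.data$value)) |>
    dplyr::summarise(
      z = mean(.data$value), n_pixels = dplyr::n(),
      .by = c("year", "bin")
    ) |>
    dplyr::mutate(bin_mid = .data$bin + bin_width / 2) |>
    dplyr::arrange(.data$year, .data$bin)
  structure(out,
    class = c("hovmoller", class(out)),
    axis = axis, bin_width = bin_width
  )
}

#' EOF decomposition of an annual cube
#'
#' Centers each pixel's series by its temporal mean (anomaly / covariance
#' EOF; set `center = FALSE` for the raw-field variant), arranges valid
#' pixels as a space x time matrix and takes its SVD. Mode `k` explains a
#' fraction `sigma_k^2 / sum(sigma^2)` of the (centered) variance; spatial
#' modes are the left singular vectors on the grid; temporal coefficients
#' are the right singular vectors scaled by the singular values. Each mode's
#' sign is fixed so that its largest-magnitude spatial loading is positive.
#'
#' @param gsvi Annual cube tibble; pixels with any invalid year are dropped
#'   from the decomposition (EOF needs a complete matrix).
#' @param n_modes Number of modes to retain (default 10); truncated with a
#'   warning if it exceeds `min(space, time)`.
#' @param center Center each pixel series by its temporal mean (default).
#' @return An object of class `eof`: `spatial` (tibble pixel x mode with
#'   `loading`), `temporal` (tibble year x mode with `coefficient`),
#'   `variance_fraction`, `singular_values`, `pixel_means`, `n_pixels`,
#'   `n_years`.
#' @export
eof_decompose <- function(gsvi, n_modes = 10, center = TRUE) {
  m <- annual_matrix(gsvi) # years x pixels
  keep <- colSums(!is.finite(m)) == 0
  if (!any(keep)) rlang::abort("no pixel has a complete series")
  m <- m[, keep, drop = FALSE]
  pix <- attr(annual_matrix(gsvi), "pixels")[keep]
  years <- as.integer(rownames(m))
  mu <- colMeans(m)
  a <- if (center) sweep(m, 2, mu) else m # time x space anomalies
  max_modes <- min(dim(a))
  if (n_modes > max_modes) {
    rlang::warn(sprintf("n_modes truncated from %d to %d", n_modes, max_modes))
    n_modes <- max_modes
  }
  sv <- svd(a)
  vf <- sv$d^2 / sum(sv$d^2)
  # sign convention: dominant spatial loading positive
  for (k in seq_len(n_modes)) {
    i_max <- which.max(abs(sv$v[, k]))
    if (sv$v[i_max, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  meta <- pixel_meta(gsvi)
  spatial <- tidyr::expand_grid(mode = seq_len(n_modes), pixel = pix) |>
    dplyr::mutate(
      loading = as.vector(sv$v[, seq_len(n_modes), drop = FALSE])
    ) |>
    dplyr::left_join(meta, by = "pixel") |>
    dplyr::relocate("pixel", .before = "mode")
  temporal <- tidyr::expand_grid(mode = seq_len(n_modes), year = years) |>
    dplyr::mutate(coefficient = as.vector(
      sv$u[, seq_len(n_modes), drop = FALSE] %*%
        diag(sv$d[seq_len(n_modes)], n_modes)
    ))
  structure(
    list(
      spatial = spatial, temporal = temporal,
      variance_fraction = vf, singular_values = sv$d,
      pixel_means = tibble::tibble(pixel = pix, mean = mu),
      n_pixels = length(pix), n_years = length(years),
      n_modes = n_modes, centered = center
    ),
    class = "eof"
  )
}

#' @export
print.eof <- function(x, ...) {
  cat(sprintf(
    "<eof> %d modes over %d pixels x %d years; mode 1 explains %.1f%%\n",
    x$n_modes, x$n_pixels, x$n_years, 100 * x$variance_fraction[1]
  ))
  invisible(x)
}

#' @rdname eof_decompose
#' @param x An `eof` object.
#' @param ... Unused.
#' @export
tidy.eof <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$variance_fraction),
    variance_fraction = x$variance_fraction,
    singular_value = x$singular_values
  )
}

#' @rdname eof_decompose
#' @export
glance.eof <- function(x, ...) {
  tibble::tibble(
    n_modes = x$n_modes, n_pixels = x$n_pixels, n_years = x$n_years,
    retained_variance = sum(x$variance_fraction[seq_len(x$n_modes)]),
    centered = x$centered
  )
}

#' Reconstruct the field from EOF modes
#'
#' @param x An `eof` object.
#' @param n_modes Number of leading modes to use (default: all retained).
#' @return Annual cube tibble with the reconstructed `value` (pixel means
#'   added back when the decomposition was centered).
#' @export
eof_reconstruct <- function(x, n_modes = x$n_modes) {
  stopifnot(inherits(x, "eof"), n_modes <= x$n_modes)
  pcs <- x$temporal |>
    dplyr::filter(.data$mode <= n_modes)
  sp <- x$spatial |>
    dplyr::filter(.data$mode <= n_modes)
  years <- sort(unique(pcs$year))
  u <- matrix(0, length(years), n_modes)
  for (k in seq_len(n_modes)) {
    u[, k] <- pcs$coefficient[pcs$mode == k]
  }
  v <- matrix(0, x$n_pixels, n_modes)
  pix <- x$pixel_means$pixel
  for (k in seq_len(n_modes)) {
    v[, k] <- sp$loading[sp$mode == k]
  }
  recon <- u %*% t(v)
  if (x$centered) recon <- sweep(recon, 2, x$pixel_means$mean, "+")
  tibble::tibble(
    pixel = rep(pix, each = length(years)),
    year = rep(years, times = length(pix)),
    value = as.vector(recon),
    valid = TRUE
  )
}
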