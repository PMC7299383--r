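# Synthetic NDVI / climate scenes with known ground truth.
#
# The generator emulates the statistical structure a growing-season greenness
# analysis has to recover: per-pixel linear trends of both signs, single step
# change points, long-memory (fGn) interannual noise with prescribed Hurst
# exponent, a within-year seasonal cycle, quality-flag dropouts, barren
# pixels, and seasonal climate anomalies with known contributions to GSVI.

#' Specify a synthetic vegetation scene
#'
#' Bundles the per-pixel ground-truth maps and scene-level settings consumed
#' by [gen_ndvi_cube()] and [gen_climate_cubes()]. Per-pixel arguments are
#' recycled across the grid, so scalars describe a homogeneous scene.
#'
#' @param nrow,ncol Grid dimensions in pixels.
#' @param years Number of calendar years (default 31, a 1982-2012-like span).
#' @param steps_per_year Observations per year (default 24, semimonthly).
#' @param baseline Mean growing-season NDVI per pixel (NDVI units).
#' @param trend Linear GSVI trend per pixel (NDVI units / year).
#' @param changepoint_year Year index (1-based) at which a step begins, or
#'   `NA` for no change point. Must lie in `4 .. years - 3` so a change-point
#'   test has support on both sides.
#' @param step_size Step height added from `changepoint_year` onward (NDVI).
#' @param hurst Hurst exponent of the interannual noise, strictly in (0, 1).
#' @param noise_sd Standard deviation of the interannual fGn noise (NDVI).
#' @param seasonal_amplitude Peak-to-trough amplitude of the within-year
#'   raised-cosine cycle over the growing window (NDVI units). The cycle is
#'   centred so its May-September mean is zero, making the annual GSVI
#'   insensitive to cycle phase.
#' @param flag_dropout_rate Probability that an observation is marked with a
#'   bad quality flag, in \[0, 1\].
#' @param barren_fraction Fraction of pixels forced to baseline 0.02 (below
#'   the 0.05 barren threshold) with zero trend and step, to exercise the
#'   barren filter.
#' @param start_year First calendar year (default 1982).
#' @param lon0,lat0,res Grid geometry, passed to [make_grid()].
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @return An object of class `synthetic_spec`.
#' @examples
#' sp <- synthetic_spec(4, 4, trend = 0.002, noise_sd = 0, seed = 1)
#' @export
synthetic_spec <- function(nrow = 10, ncol = 10, years = 31,
                           steps_per_year = 24,
                           baseline = 0.3, trend = 0,
                           changepoint_year = NA, step_size = 0,
                           hurst = 0.5, noise_sd = 0.02,
                           seasonal_amplitude = 0.15,
                           flag_dropout_rate = 0,
                           barren_fraction = 0,
                           start_year = 1982,
                           lon0 = 80, lat0 = 40, res = 0.1,
                           seed = 1L) {
  stopifnot(
    years >= 4, steps_per_year %in% c(12, 24, 36, 48),
    flag_dropout_rate >= 0, flag_dropout_rate <= 1,
    barren_fraction >= 0, barren_fraction <= 1
  )
  grid <- make_grid(nrow, ncol, lon0, lat0, res)
  np <- nrow(grid)
  rec <- function(x) rep_len(as.numeric(x), np)
  hurst <- rec(hurst)
  noise_sd <- rec(noise_sd)
  cp <- rep_len(as.numeric(changepoint_year), np)
  if (any(!(hurst > 0 & hurst < 1))) {
    rlang::abort("all `hurst` values must lie strictly in (0, 1)")
  }
  if (any(noise_sd < 0)) rlang::abort("`noise_sd` must be nonnegative")
  if (any(!is.na(cp) & (cp < 4 | cp > years - 3))) {
    rlang::abort("`changepoint_year` indices must lie in 4 .. years - 3")
  }
  baseline <- rec(baseline)
  if (barren_fraction > 0) {
    n_bar <- round(barren_fraction * np)
    if (n_bar > 0) {
      bar <- seq_len(n_bar) # deterministic: first pixels are barren
      baseline[bar] <- 0.02
    }
  } else {
    bar <- integer(0)
  }
  trend <- rec(trend)
  step_size <- rec(step_size)
  if (length(bar) > 0) {
    trend[bar] <- 0
    step_size[bar] <- 0
    cp[bar] <- NA
  }
  structure(
    list(
      grid = grid, years = years, steps_per_year = steps_per_year,
      baseline = baseline, trend = trend, changepoint_year = cp,
      step_size = step_size, hurst = hurst, noise_sd = noise_sd,
      seasonal_amplitude = seasonal_amplitude,
      flag_dropout_rate = flag_dropout_rate,
      barren_pixels = bar, start_year = start_year, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(
    "<synthetic_spec> ", max(x$grid$row), "x", max(x$grid$col), " pixels, ",
    x$years, " years x ", x$steps_per_year, " steps, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Raised-cosine seasonal cycle, zero-mean over the growing window so that the
# May-September composite recovers the annual level exactly.
#' @keywords internal
seasonal_cycle <- function(steps_per_year, amplitude, growing = 5:9) {
  month <- ceiling(seq_len(steps_per_year) / (steps_per_year / 12))
  s <- numeric(steps_per_year)
  in_gs <- month %in% growing
  k <- sum(in_gs)
  pos <- seq_len(k)
  s[in_gs] <- amplitude * 0.5 * (1 - cos(2 * pi * (pos - 0.5) / k))
  s[in_gs] <- s[in_gs] - mean(s[in_gs])
  list(cycle = s, month = month)
}

#' Generate a semimonthly NDVI cube with ground truth
#'
#' Per pixel, observations follow
#' `value(t) = baseline + trend * (year - 1) + step * [year >= changepoint]
#'  + seasonal(t) + fGn_year(H) * sd`,
#' where the interannual fGn noise is constant within a year (it perturbs the
#' annual growing-season level, which is what the Hurst estimator must see)
#' and `seasonal(t)` is a raised cosine with zero May-September mean. Values
#' are clipped to the physical NDVI range \[-0.2, 1\]; the number of clipped
#' cells is recorded in `attr(cube, "n_clipped")`. A share
#' `flag_dropout_rate` of observations receives quality flag 0 (all others
#' flag 1), to be removed by [apply_quality_mask()].
#'
#' @param spec A [synthetic_spec()].
#' @param climate Optional result of [gen_climate_cubes()]; when supplied the
#'   per-pixel growing-season temperature and precipitation anomalies are
#'   added to the annual level with the climate object's `beta_t`, `beta_p`
#'   coefficients.
#' @return A list with elements `cube` (long tibble: pixel, row, col, lon,
#'   lat, year, step, month, value, flag, valid) and `truth` (list with
#'   per-pixel map tibble and the annual true GSVI tibble).
#' @examples
#' sc <- gen_ndvi_cube(synthetic_spec(3, 3, noise_sd = 0, seed = 1))
#' head(sc$cube)
#' @export
gen_ndvi_cube <- function(spec, climate = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  np <- nrow(spec$grid)
  ny <- spec$years
  spy <- spec$steps_per_year
  set.seed(spec$seed)

  # annual true level per pixel (years x pixels)
  yr <- seq_len(ny)
  level <- vapply(seq_len(np), function(p) {
    lv <- spec$baseline[p] + spec$trend[p] * (yr - 1)
    if (!is.na(spec$changepoint_year[p])) {
      lv <- lv + spec$step_size[p] * (yr >= spec$changepoint_year[p])
    }
    lv
  }, numeric(ny))

  if (!is.null(climate)) {
    stopifnot(inherits(climate, "synthetic_climate"))
    level <- level +
      outer(rep(1, ny), climate$beta_t) * t(climate$gst_anom) +
      outer(rep(1, ny), climate$beta_p) * t(climate$gsp_anom)
  }

  noise <- vapply(seq_len(np), function(p) {
    if (spec$noise_sd[p] > 0) {
      gen_fgn(ny, spec$hurst[p], spec$noise_sd[p])
    } else {
      numeric(ny)
    }
  }, numeric(ny))
  annual <- level + noise

  sc <- seasonal_cycle(spy, spec$seasonal_amplitude)
  # expand to (ny*spy) x np
  vals <- annual[rep(yr, each = spy), , drop = FALSE] +
    rep(sc$cycle, times = ny)
  n_clip <- sum(vals < -0.2 | vals > 1)
  vals <- pmin(pmax(vals, -0.2), 1)

  nt <- ny * spy
  flag <- matrix(1L, nt, np)
  if (spec$flag_dropout_rate > 0) {
    flag[stats::runif(nt * np) < spec$flag_dropout_rate] <- 0L
  }

  cube <- tibble::tibble(
    pixel = rep(spec$grid$pixel, each = nt),
    row = rep(spec$grid$row, each = nt),
    col = rep(spec$grid$col, each = nt),
    lon = rep(spec$grid$lon, each = nt),
    lat = rep(spec$grid$lat, each = nt),
    year = rep(rep(spec$start_year + yr - 1, each = spy), times = np),
    step = rep(rep(seq_len(spy), times = ny), times = np),
    month = rep(rep(sc$month, times = ny), times = np),
    value = as.vector(vals),
    flag = as.vector(flag),
    valid = TRUE
  )
  attr(cube, "n_clipped") <- n_clip

  truth <- list(
    pixels = tibble::tibble(
      pixel = spec$grid$pixel,
      baseline = spec$baseline,
      trend = spec$trend,
      changepoint_year = ifelse(is.na(spec$changepoint_year), NA_real_,
        spec$start_year + spec$changepoint_year - 1
      ),
      step_size = spec$step_size,
      hurst = spec$hurst,
      noise_sd = spec$noise_sd,
      barren = spec$grid$pixel %in% spec$barren_pixels
    ),
    annual = tibble::tibble(
      pixel = rep(spec$grid$pixel, each = ny),
      year = rep(spec$start_year + yr - 1, times = np),
      gsvi_true = as.vector(annual)
    )
  )
  if (!is.null(climate)) {
    truth$pixels$beta_t <- climate$beta_t
    truth$pixels$beta_p <- climate$beta_p
    truth$pixels$contribution_t_true <- climate$contribution_t_true
  }
  list(cube = cube, truth = truth)
}

#' Generate monthly climate cubes with known GSVI coupling
#'
#' Produces monthly temperature and precipitation cubes on a grid coarser by
#' `coarsen`, with independent interannual anomalies per seasonal window
#' (preseason, growing season, postseason). The growing-season anomalies are
#' returned per fine pixel so [gen_ndvi_cube()] can couple them into GSVI
#' with coefficients `beta_t` and `beta_p`; under independent anomalies the
#' true relative temperature contribution is
#' `beta_t^2 var(GST) / (beta_t^2 var(GST) + beta_p^2 var(GSP))`.
#'
#' @param spec A [synthetic_spec()].
#' @param beta_t,beta_p Per-pixel coupling coefficients (recycled): NDVI per
#'   degC and NDVI per mm.
#' @param coarsen Integer >= 1; climate grid is coarser by this factor.
#' @param temp_mean Annual-mean temperature level (degC).
#' @param precip_month Mean monthly precipitation (mm).
#' @param gst_anom_sd,gsp_anom_sd SDs of the growing-season window anomalies
#'   (degC for the window mean; mm for the window sum).
#' @return An object of class `synthetic_climate`: monthly `temp` and
#'   `precip` cubes (coarse grid), per-fine-pixel anomaly matrices, the beta
#'   maps, and the closed-form true temperature contribution.
#' @examples
#' cl <- gen_climate_cubes(synthetic_spec(4, 4, seed = 2), beta_t = 0.01)
#' head(cl$temp)
#' @export
gen_climate_cubes <- function(spec, beta_t = 0, beta_p = 0, coarsen = 1,
                              temp_mean = 5, precip_month = 60,
                              gst_anom_sd = 0.8, gsp_anom_sd = 30) {
  stopifnot(inherits(spec, "synthetic_spec"), coarsen >= 1)
  np <- nrow(spec$grid)
  beta_t <- rep_len(as.numeric(beta_t), np)
  beta_p <- rep_len(as.numeric(beta_p), np)
  if (length(beta_t) != np || length(beta_p) != np) {
    rlang::abort("beta map shape does not match the grid")
  }
  ny <- spec$years
  nr <- max(spec$grid$row)
  nc <- max(spec$grid$col)
  res_f <- spec$grid$lon[2] - spec$grid$lon[1]
  if (!is.finite(res_f) || res_f <= 0) res_f <- 0.1
  crs <- ceiling(nr / coarsen)
  ccs <- ceiling(nc / coarsen)
  cgrid <- make_grid(crs, ccs,
    lon0 = min(spec$grid$lon) - res_f / 2,
    lat0 = max(spec$grid$lat) + res_f / 2,
    res = res_f * coarsen
  )
  ncp <- nrow(cgrid)
  set.seed(spec$seed + 1L)

  windows <- list(pre = 1:4, gs = 5:9, post = 10:12)
  # window anomalies: [coarse pixel, year, window], independent draws
  t_anom <- array(stats::rnorm(ncp * ny * 3), c(ncp, ny, 3))
  t_anom[, , 2] <- t_anom[, , 2] * gst_anom_sd
  t_anom[, , c(1, 3)] <- t_anom[, , c(1, 3)] * gst_anom_sd
  p_anom <- array(stats::rnorm(ncp * ny * 3), c(ncp, ny, 3))
  p_anom[, , 2] <- p_anom[, , 2] * gsp_anom_sd
  p_anom[, , c(1, 3)] <- p_anom[, , c(1, 3)] * gsp_anom_sd

  month_of <- rep(1:12, times = ny)
  win_of <- ifelse(month_of <= 4, 1L, ifelse(month_of <= 9, 2L, 3L))
  year_i <- rep(seq_len(ny), each = 12)
  # mild sinusoidal annual temperature cycle
  t_cycle <- temp_mean + 8 * cos(2 * pi * (month_of - 7) / 12)
  nmon <- 12L * ny
  wlen <- c(4, 5, 3)

  tvals <- matrix(0, nmon, ncp)
  pvals <- matrix(0, nmon, ncp)
  for (j in seq_len(ncp)) {
    ta <- t_anom[j, , ]
    pa <- p_anom[j, , ]
    tvals[, j] <- t_cycle + ta[cbind(year_i, win_of)]
    # precipitation: window-sum anomaly spread evenly over window months
    pvals[, j] <- precip_month + pa[cbind(year_i, win_of)] / wlen[win_of]
  }
  pvals <- pmax(pvals, 0)

  mk_cube <- function(vals) {
    tibble::tibble(
      pixel = rep(cgrid$pixel, each = nmon),
      row = rep(cgrid$row, each = nmon),
      col = rep(cgrid$col, each = nmon),
      lon = rep(cgrid$lon, each = nmon),
      lat = rep(cgrid$lat, each = nmon),
      year = rep(spec$start_year + year_i - 1, times = ncp),
      month = rep(month_of, times = ncp),
      value = as.vector(vals),
      valid = TRUE
    )
  }

  # map each fine pixel to its covering coarse cell
  cidx <- (pmin(ceiling(spec$grid$row / coarsen), crs) - 1) * ccs +
    pmin(ceiling(spec$grid$col / coarsen), ccs)
  gst_anom <- t_anom[cidx, , 2, drop = TRUE]
  gsp_anom <- p_anom[cidx, , 2, drop = TRUE]
  if (is.null(dim(gst_anom))) {
    gst_anom <- matrix(gst_anom, nrow = np)
    gsp_anom <- matrix(gsp_anom, nrow = np)
  }

  denom <- beta_t^2 * gst_anom_sd^2 + beta_p^2 * gsp_anom_sd^2
  contribution_t_true <- ifelse(denom > 0,
    100 * beta_t^2 * gst_anom_sd^2 / denom, NA_real_
  )

  structure(
    list(
      temp = mk_cube(tvals), precip = mk_cube(pvals),
      beta_t = beta_t, beta_p = beta_p,
      gst_anom = gst_anom, gsp_anom = gsp_anom,
      gst_anom_sd = gst_anom_sd, gsp_anom_sd = gsp_anom_sd,
      contribution_t_true = contribution_t_true,
      fine_grid = spec$grid, coarse_grid = cgrid
    ),
    class = "synthetic_climate"
  )
}
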