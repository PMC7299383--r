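# End-to-end orchestration of the analysis stages.

#' Configure a full pipeline run
#'
#' Collects the analysis settings with the study defaults: May-September
#' growing season, alpha 0.05, Savitzky-Golay window 7 / order 2, barren
#' threshold 0.05, 10 EOF modes, three 10-year decade windows.
#'
#' @param windows A [season_windows()].
#' @param alpha Significance level used by every test.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param smooth Apply Savitzky-Golay smoothing to the semimonthly cube.
#' @param barren_threshold Barren-pixel NDVI cutoff.
#' @param min_gs_obs Minimum valid growing-season observations per year.
#' @param n_eof_modes Retained EOF modes.
#' @param decades Named list of decade year ranges, or `NULL` to derive
#'   three 10-year windows from the cube's first year.
#' @param keep_flags Reliable quality-flag set.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(windows = season_windows(), alpha = 0.05,
                            sg_window = 7, sg_polyorder = 2, smooth = TRUE,
                            barren_threshold = 0.05, min_gs_obs = 7,
                            n_eof_modes = 10, decades = NULL,
                            keep_flags = c(1, 2, 3, 5), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, barren_threshold >= 0)
  structure(
    list(
      windows = windows, alpha = alpha, sg_window = sg_window,
      sg_polyorder = sg_polyorder, smooth = smooth,
      barren_threshold = barren_threshold, min_gs_obs = min_gs_obs,
      n_eof_modes = n_eof_modes, decades = decades,
      keep_flags = keep_flags, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline on an NDVI cube
#'
#' Sequences quality masking, smoothing, barren filtering, growing-season
#' compositing, the trend / persistence / change-point maps, the EOF
#' decomposition, decade comparisons, and (when climate cubes are given)
#' the Spearman and LMG attribution stage. Returns every stage result plus
#' a manifest of summary statistics.
#'
#' @param ndvi Semimonthly NDVI cube tibble (with `flag` column).
#' @param config A [pipeline_config()].
#' @param temp,precip Optional monthly climate cubes (any grid; regridded
#'   to the NDVI grid by nearest neighbour).
#' @param zones Optional tibble with `pixel`, `zone`.
#' @return A list of class `pipeline_result` with elements `gsvi`, `trend`,
#'   `persistence`, `changepoints`, `eof`, `decades`, `attribution` (or
#'   `NULL`), `zonal` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(ndvi, config = pipeline_config(),
                         temp = NULL, precip = NULL, zones = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage `", name, "` failed: ",
        conditionMessage(e)))
    })
  }
  masked <- stage("quality_mask",
    apply_quality_mask(ndvi, keep_flags = config$keep_flags))
  if (config$smooth) {
    masked <- stage("smooth",
      smooth_cube(masked, config$sg_window, config$sg_polyorder))
  }
  masked <- stage("mask_barren", mask_barren(masked, config$barren_threshold))
  n_barren <- attr(masked, "n_barren")
  gsvi <- stage("composite_gsvi",
    composite_gsvi(masked, config$windows, config$min_gs_obs))

  trend <- stage("trend_map", trend_map(gsvi, config$alpha))
  pers <- stage("persistence_map",
    persistence_map(gsvi, trend, config$alpha, zones = zones))
  cps <- stage("changepoint_map", changepoint_map(gsvi, config$alpha))
  eof <- stage("eof", eof_decompose(gsvi, config$n_eof_modes))

  decades <- config$decades
  if (is.null(decades)) {
    y0 <- min(gsvi$year)
    decades <- list(
      d1 = y0:(y0 + 9), d2 = (y0 + 10):(y0 + 19), d3 = (y0 + 20):(y0 + 29)
    )
  }
  dec <- stage("decades", decade_compare(gsvi, decades))

  attribution <- NULL
  if (!is.null(temp) && !is.null(precip)) {
    grid <- pixel_meta(gsvi)
    tr <- stage("regrid_temp", regrid_nearest(temp, grid))
    pr <- stage("regrid_precip", regrid_nearest(precip, grid))
    clim <- stage("seasonal_climate",
      seasonal_climate(tr, pr, config$windows))
    attribution <- stage("attribution",
      attribution_map(gsvi, clim, "growing"))
  }

  zonal <- if (!is.null(zones)) {
    stage("zonal", zonal_summary(gsvi, trend, zones))
  }

  vegetated <- trend$pixel[!is.na(trend$class)]
  manifest <- list(
    seed = config$seed, alpha = config$alpha,
    n_pixels = nrow(pixel_meta(ndvi)),
    n_barren = n_barren,
    n_vegetated = length(vegetated),
    trend_shares = attr(trend, "summary"),
    mean_h = attr(pers, "mean_h"),
    class_shares = attr(pers, "class_shares"),
    changepoint_histogram = attr(cps, "histogram"),
    eof_variance = eof$variance_fraction[seq_len(eof$n_modes)],
    decade_means = dec$means
  )
  structure(
    list(
      gsvi = gsvi, trend = trend, persistence = pers,
      changepoints = cps, eof = eof, decades = dec,
      attribution = attribution, zonal = zonal, manifest = manifest
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<pipeline_result> %d pixels (%d vegetated, %d barren); mean H = %.3f\n",
    m$n_pixels, m$n_vegetated, m$n_barren, m$mean_h
  ))
  invisible(x)
}
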