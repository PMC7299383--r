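# Theil-Sen / Mann-Kendall trend statistics, CV, decades, zonal summaries.

#' Theil-Sen slope of a series
#'
#' The median of all `n(n-1)/2` pairwise slopes `(y_i - y_j)/(t_i - t_j)`
#' over `i > j` — a trend estimator robust to outliers. Time defaults to the
#' integer observation index, so for annual series the slope is in value
#' units per year. Even slope counts use the midpoint-average median.
#'
#' @param y Numeric series; `NA`s are dropped.
#' @param t Time stamps matching `y` (default: index).
#' @return The slope, or `NA` with fewer than 2 valid points.
#' @examples
#' theil_sen(c(1, 2, 3, 4, 5)) # 1
#' @export
theil_sen <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]
  t <- t[ok]
  n <- length(y)
  if (n < 2 || length(unique(t)) < 2) {
    return(NA_real_)
  }
  ij <- utils::combn(n, 2)
  dt <- t[ij[2, ]] - t[ij[1, ]]
  stats::median((y[ij[2, ]] - y[ij[1, ]])[dt != 0] / dt[dt != 0])
}

#' Mann-Kendall trend test
#'
#' Computes `S = sum_{i<j} sgn(y_j - y_i)` and a two-sided p-value from the
#' normal approximation with the tie-corrected variance
#' `[n(n-1)(2n+5) - sum t(t-1)(2t+5)] / 18` and a +/-1 continuity
#' correction. With all values tied the variance is zero; `p = 1` is
#' returned with `degenerate = TRUE`.
#'
#' @param y Numeric series; `NA`s are dropped.
#' @return A list: `s`, `var_s`, `p`, `n`, `degenerate`.
#' @examples
#' mann_kendall(1:10)$s # 45
#' @export
mann_kendall <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 4) {
    return(list(
      s = NA_real_, var_s = NA_real_, p = NA_real_,
      n = n, degenerate = TRUE
    ))
  }
  d <- sign(outer(y, y, "-")) # d[j, i] = sgn(y_j - y_i)
  s <- sum(d[lower.tri(d)])
  tt <- table(y)
  tt <- tt[tt > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
    sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  if (var_s <= 0) {
    return(list(s = s, var_s = 0, p = 1, n = n, degenerate = TRUE))
  }
  z <- (s - sign(s)) / sqrt(var_s)
  list(
    s = s, var_s = var_s,
    p = 2 * stats::pnorm(-abs(z)), n = n, degenerate = FALSE
  )
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; a
#' relative-variability measure for strictly positive quantities such as
#' GSVI.
#'
#' @param y Numeric series; `NA`s are dropped.
#' @return Percent CV, or `NA` when the mean is zero or n < 2.
#' @export
cv_percent <- function(y) {
  y <- y[is.finite(y)]
  if (length(y) < 2) {
    return(NA_real_)
  }
  m <- mean(y)
  if (m == 0) {
    return(NA_real_)
  }
  100 * stats::sd(y) / m
}

#' Per-pixel trend map of an annual cube
#'
#' Computes the Theil-Sen slope, Mann-Kendall statistic and p-value, and CV
#' for every pixel of an annual (GSVI) cube, and partitions pixels into
#' significant-positive / significant-negative / nonsignificant classes at
#' level `alpha`.
#'
#' @param gsvi Annual cube tibble (from [composite_gsvi()]).
#' @param alpha Significance level for the Mann-Kendall test.
#' @param min_years Minimum valid years per pixel.
#' @return A tibble, one row per pixel: `slope`, `mk_s`, `mk_p`, `cv`,
#'   `n_used`, `class` (factor positive/negative/nonsignificant, `NA` for
#'   pixels with too few data). Class counts and shares are attached as
#'   `attr(, "summary")`.
#' @export
trend_map <- function(gsvi, alpha = 0.05, min_years = 4) {
  m <- annual_matrix(gsvi)
  res <- purrr::map(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    n <- sum(is.finite(y))
    if (n < min_years) {
      return(tibble::tibble(
        slope = NA_real_, mk_s = NA_real_, mk_p = NA_real_,
        cv = NA_real_, n_used = n
      ))
    }
    mk <- mann_kendall(y)
    tibble::tibble(
      slope = theil_sen(y), mk_s = mk$s, mk_p = mk$p,
      cv = cv_percent(y), n_used = n
    )
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(
    tibble::tibble(pixel = attr(m, "pixels")), res
  ) |>
    dplyr::mutate(class = factor(
      dplyr::case_when(
        is.na(.data$mk_p) ~ NA_character_,
        .data$mk_p < alpha & .data$slope > 0 ~ "positive",
        .data$mk_p < alpha & .data$slope < 0 ~ "negative",
        .default = "nonsignificant"
      ),
      levels = c("positive", "negative", "nonsignificant")
    ))
  out <- dplyr::left_join(pixel_meta(gsvi), out, by = "pixel")
  cnt <- table(out$class)
  attr(out, "summary") <- tibble::tibble(
    class = names(cnt),
    n = as.integer(cnt),
    share = as.numeric(cnt) / sum(cnt) * 100
  )
  attr(out, "alpha") <- alpha
  out
}

#' Compare decade windows of the spatial-mean annual series
#'
#' Splits the spatial-mean GSVI series into non-overlapping year windows
#' (e.g. 1982-1991 / 1992-2001 / 2002-2011) and compares every window pair
#' with Welch's unequal-variance t-test.
#'
#' @param gsvi Annual cube tibble.
#' @param windows Named list of year ranges, e.g.
#'   `list(d1 = 1982:1991, d2 = 1992:2001)`.
#' @return A list: `means` (per-window mean, sd, n of the spatial-mean
#'   series), `tests` (pairwise Welch t, df, p), `series` (the spatial-mean
#'   annual values with their window label, the paired scatter data).
#' @export
decade_compare <- function(gsvi, windows) {
  stopifnot(length(windows) >= 2)
  yrs <- unlist(windows)
  if (anyDuplicated(yrs)) rlang::abort("decade windows must not overlap")
  sm <- gsvi |>
    dplyr::filter(.data$valid) |>
    dplyr::summarise(gsvi = mean(.data$value), .by = "year")
  lab <- rep(NA_character_, nrow(sm))
  for (w in names(windows)) lab[sm$year %in% windows[[w]]] <- w
  series <- dplyr::mutate(sm, window = lab) |>
    dplyr::filter(!is.na(.data$window))
  means <- series |>
    dplyr::summarise(
      mean = mean(.data$gsvi), sd = stats::sd(.data$gsvi),
      n = dplyr::n(), .by = "window"
    )
  prs <- utils::combn(names(windows), 2)
  tests <- purrr::map(seq_len(ncol(prs)), function(k) {
    a <- series$gsvi[series$window == prs[1, k]]
    b <- series$gsvi[series$window == prs[2, k]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate windows: identical constants compare as equal
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      ht <- list(
        statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
        parameter = NA_real_, p.value = if (eq) 1 else 0
      )
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
    }
    tibble::tibble(
      window_a = prs[1, k], window_b = prs[2, k],
      t = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value
    )
  }) |> purrr::list_rbind()
  list(means = means, tests = tests, series = series)
}

#' Zonal summaries over an ecoregion raster
#'
#' Per zone: the spatial-mean annual series, its OLS slope over the full
#' period and over a sub-period, the CV of the zone-mean series, and counts
#' of significantly greening / browning pixels from a [trend_map()] result.
#'
#' @param gsvi Annual cube tibble.
#' @param trend A [trend_map()] result aligned with `gsvi`.
#' @param zones Tibble with `pixel` and `zone` columns (a label raster in
#'   tidy form).
#' @param sub_years Year range for the sub-period slope (default: the first
#'   10 years present).
#' @return A tibble, one row per zone.
#' @export
zonal_summary <- function(gsvi, trend, zones, sub_years = NULL) {
  stopifnot(all(c("pixel", "zone") %in% names(zones)))
  if (is.null(sub_years)) {
    y0 <- sort(unique(gsvi$year))
    sub_years <- y0[seq_len(min(10, length(y0)))]
  }
  g <- dplyr::inner_join(gsvi, zones[, c("pixel", "zone")], by = "pixel")
  tr <- dplyr::inner_join(trend, zones[, c("pixel", "zone")], by = "pixel")
  ols_slope <- function(y, x) {
    if (length(y) < 2) {
      return(NA_real_)
    }
    unname(stats::coef(stats::lm(y ~ x))[2])
  }
  zm <- g |>
    dplyr::filter(.data$valid) |>
    dplyr::summarise(gsvi = mean(.data$value), .by = c("zone", "year"))
  per_zone <- zm |>
    dplyr::summarise(
      mean_gsvi = mean(.data$gsvi),
      slope_full = ols_slope(.data$gsvi, .data$year),
      slope_sub = ols_slope(
        .data$gsvi[.data$year %in% sub_years],
        .data$year[.data$year %in% sub_years]
      ),
      cv = cv_percent(.data$gsvi),
      n_years = dplyr::n(),
      .by = "zone"
    )
  cnts <- tr |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      n_sig_positive = sum(.data$class == "positive", na.rm = TRUE),
      n_sig_negative = sum(.data$class == "negative", na.rm = TRUE),
      .by = "zone"
    )
  out <- dplyr::full_join(per_zone, cnts, by = "zone") |>
    dplyr::arrange(.data$zone)
  out$empty <- is.na(out$n_years) | out$n_years == 0
  out
}
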