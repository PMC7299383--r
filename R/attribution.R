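# Seasonal climate windows, Spearman maps, LMG relative importance.

#' Seasonal climate summaries on the vegetation grid
#'
#' Aggregates monthly temperature and precipitation cubes into per-pixel,
#' per-year seasonal summaries: window means for temperature (PreT, GST,
#' PostT) and window sums for precipitation (PreP, GSP, PostP). A pixel-year
#' missing any month of a window is invalid for that window.
#'
#' @param temp,precip Monthly cubes on the vegetation grid (regrid first
#'   with [regrid_nearest()] if coarser).
#' @param windows A [season_windows()].
#' @return A tibble: `pixel`, `year`, `pre_t`, `gs_t`, `post_t`, `pre_p`,
#'   `gs_p`, `post_p`.
#' @export
seasonal_climate <- function(temp, precip, windows = season_windows()) {
  assert_cube(temp, c("year", "month"))
  assert_cube(precip, c("year", "month"))
  win_of <- function(m) {
    dplyr::case_when(
      m %in% windows$preseason ~ "pre",
      m %in% windows$growing ~ "gs",
      m %in% windows$postseason ~ "post",
      .default = NA_character_
    )
  }
  agg <- function(cube, fun, suffix) {
    cube |>
      dplyr::mutate(window = win_of(.data$month)) |>
      dplyr::filter(!is.na(.data$window)) |>
      dplyr::summarise(
        value = if (all(.data$valid)) fun(.data$value) else NA_real_,
        n_months = dplyr::n(),
        .by = c("pixel", "year", "window")
      ) |>
      dplyr::mutate(window = paste0(.data$window, suffix)) |>
      dplyr::select(!"n_months") |>
      tidyr::pivot_wider(names_from = "window", values_from = "value")
  }
  dplyr::full_join(
    agg(temp, mean, "_t"), agg(precip, sum, "_p"),
    by = c("pixel", "year")
  ) |>
    dplyr::arrange(.data$pixel, .data$year)
}

#' Spearman correlation map of GSVI against a climate driver
#'
#' Per-pixel Spearman rank correlation (midranks on ties) of the annual
#' GSVI series against one seasonal climate variable, plus the shares of
#' vegetated pixels with positive vs. negative correlation.
#'
#' @param gsvi Annual cube tibble.
#' @param climate A [seasonal_climate()] tibble.
#' @param variable One of `"pre_t"`, `"gs_t"`, `"post_t"`, `"pre_p"`,
#'   `"gs_p"`, `"post_p"`.
#' @param min_years Minimum overlapping valid years per pixel (default 5).
#' @return Tibble per pixel with `r`; `attr(, "sign_shares")` gives the
#'   positive/negative percentages.
#' @export
spearman_map <- function(gsvi, climate, variable, min_years = 5) {
  stopifnot(variable %in% names(climate))
  g <- gsvi |>
    dplyr::filter(.data$valid) |>
    dplyr::select("pixel", "year", gsvi = "value") |>
    dplyr::inner_join(
      dplyr::select(climate, "pixel", "year",
        driver = dplyr::all_of(variable)
      ),
      by = c("pixel", "year")
    ) |>
    dplyr::filter(is.finite(.data$driver))
  out <- g |>
    dplyr::summarise(
      r = if (dplyr::n() >= min_years &&
        stats::sd(.data$gsvi) > 0 && stats::sd(.data$driver) > 0) {
        stats::cor(.data$gsvi, .data$driver, method = "spearman")
      } else {
        NA_real_
      },
      n_used = dplyr::n(),
      .by = "pixel"
    )
  def <- out$r[!is.na(out$r)]
  attr(out, "sign_shares") <- tibble::tibble(
    sign = c("positive", "negative"),
    n = c(sum(def > 0), sum(def < 0)),
    share = 100 * c(sum(def > 0), sum(def < 0)) / max(length(def), 1)
  )
  attr(out, "variable") <- variable
  out
}

# R^2 of an OLS fit of y on the columns of x (possibly none).
#' @keywords internal
subset_r2 <- function(y, x) {
  if (is.null(x) || ncol(x) == 0) {
    return(0)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' LMG relative-importance decomposition
#'
#' Decomposes the explained variance (R^2) of an OLS fit of a response on
#' correlated predictors into nonnegative per-predictor contributions: each
#' predictor's share is its sequential R^2 increment averaged over all
#' orderings of predictor entry (computed by subset enumeration, feasible
#' for up to ~6 predictors). Raw shares sum to the full-model R^2;
#' `normalized` rescales them to sum to 100.
#'
#' @param y Response vector.
#' @param x Numeric matrix or data frame of predictors (named columns).
#' @return A list: `raw` (named shares summing to R^2), `normalized`
#'   (percent, summing to 100), `r_squared`, `ok` (FALSE on degenerate
#'   input: zero R^2 or collinear predictors).
#' @examples
#' x <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("t", "p")))
#' y <- x[, 1] + 0.5 * x[, 2] + rnorm(30, 0, 0.1)
#' lmg_importance(y, x)$normalized
#' @export
lmg_importance <- function(y, x) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(p >= 1, nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  ok_rows <- stats::complete.cases(y, x)
  y <- y[ok_rows]
  x <- x[ok_rows, , drop = FALSE]
  bad <- list(
    raw = stats::setNames(rep(NA_real_, p), colnames(x)),
    normalized = stats::setNames(rep(NA_real_, p), colnames(x)),
    r_squared = NA_real_, ok = FALSE
  )
  if (length(y) < p + 2 || stats::sd(y) == 0) {
    return(bad)
  }
  if (qr(cbind(1, x))$rank < p + 1) {
    return(bad) # collinear predictors
  }
  # R^2 for every predictor subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (s in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(s, 2^(seq_len(p) - 1)) > 0)
    r2[s + 1] <- subset_r2(y, x[, cols, drop = FALSE])
  }
  full <- r2[2^p]
  if (full <= 0) {
    bad$r_squared <- full
    return(bad)
  }
  shares <- numeric(p)
  others_fact <- factorial(p - 1)
  for (j in seq_len(p)) {
    bit_j <- 2^(j - 1)
    acc <- 0
    for (s in 0:(2^p - 1)) {
      if (bitwAnd(s, bit_j) > 0) next
      k <- sum(bitwAnd(s, 2^(seq_len(p) - 1)) > 0)
      w <- factorial(k) * factorial(p - 1 - k) / others_fact
      acc <- acc + w * (r2[bitwOr(s, bit_j) + 1] - r2[s + 1])
    }
    shares[j] <- acc / p
  }
  names(shares) <- colnames(x)
  list(
    raw = shares,
    normalized = 100 * shares / sum(shares),
    r_squared = full, ok = TRUE
  )
}

#' Temperature vs. precipitation contributions for one pixel
#'
#' Two-predictor LMG decomposition of the pixel's GSVI against a seasonal
#' temperature and precipitation pair, reported as percentages summing to
#' 100.
#'
#' @param gsvi,temp,precip Aligned numeric series for one pixel.
#' @return A list: `contribution_t`, `contribution_p` (percent),
#'   `r_squared`, `ok`.
#' @export
lmg_contributions <- function(gsvi, temp, precip) {
  res <- lmg_importance(gsvi, cbind(t = temp, p = precip))
  list(
    contribution_t = unname(res$normalized["t"]),
    contribution_p = unname(res$normalized["p"]),
    r_squared = res$r_squared, ok = res$ok
  )
}

#' Per-pixel attribution map for one seasonal window
#'
#' Runs [lmg_contributions()] on every pixel with the chosen window's
#' temperature/precipitation pair, plus Spearman correlations for both
#' drivers.
#'
#' @param gsvi Annual cube tibble.
#' @param climate A [seasonal_climate()] tibble.
#' @param window `"growing"`, `"preseason"` or `"postseason"`.
#' @param min_years Minimum overlapping years per pixel (default 6).
#' @return Tibble per pixel: `contribution_t`, `contribution_p`,
#'   `r_squared`, `r_t`, `r_p`.
#' @export
attribution_map <- function(gsvi, climate,
                            window = c("growing", "preseason", "postseason"),
                            min_years = 6) {
  window <- match.arg(window)
  pre <- c(growing = "gs", preseason = "pre", postseason = "post")[[window]]
  vt <- paste0(pre, "_t")
  vp <- paste0(pre, "_p")
  g <- gsvi |>
    dplyr::filter(.data$valid) |>
    dplyr::select("pixel", "year", gsvi = "value") |>
    dplyr::inner_join(
      dplyr::select(climate, "pixel", "year",
        temp = dplyr::all_of(vt), precip = dplyr::all_of(vp)
      ),
      by = c("pixel", "year")
    ) |>
    dplyr::filter(is.finite(.data$temp), is.finite(.data$precip))
  out <- g |>
    dplyr::summarise(
      res = list(if (dplyr::n() >= min_years) {
        lmg_contributions(.data$gsvi, .data$temp, .data$precip)
      } else {
        list(
          contribution_t = NA_real_, contribution_p = NA_real_,
          r_squared = NA_real_, ok = FALSE
        )
      }),
      r_t = if (dplyr::n() >= min_years && stats::sd(.data$gsvi) > 0 &&
        stats::sd(.data$temp) > 0) {
        stats::cor(.data$gsvi, .data$temp, method = "spearman")
      } else {
        NA_real_
      },
      r_p = if (dplyr::n() >= min_years && stats::sd(.data$gsvi) > 0 &&
        stats::sd(.data$precip) > 0) {
        stats::cor(.data$gsvi, .data$precip, method = "spearman")
      } else {
        NA_real_
      },
      .by = "pixel"
    ) |>
    tidyr::unnest_wider("res")
  attr(out, "window") <- window
  out
}
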