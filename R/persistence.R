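# Rescaled-range Hurst estimation and the six-class future-trend map.

#' Rescaled-range (R/S) Hurst exponent
#'
#' The series of length `N` is split into disjoint segments of length
#' `n = N, floor(N/2), floor(N/4), ...` down to `min_segment`. For each
#' segment the mean is removed, deviations are accumulated, and the rescaled
#' range `R/S` is formed from the range of the cumulative deviations and the
#' population (1/n) standard deviation. `R/S` is averaged over the segments
#' of each length, and `H` is the slope of the least-squares fit of
#' `log(R/S)` on `log(n)` (`R/S = C * n^H`). Trailing observations that do
#' not fill a segment are dropped.
#'
#' Zero-variance segments are excluded; lengths with no usable segment are
#' dropped; with fewer than 3 usable lengths the result is flagged
#' unreliable. Estimates outside (0, 1) are possible for short series and
#' are retained numerically but flagged.
#'
#' @param x Numeric series (gaps should be interpolated upstream; `NA`s are
#'   dropped here, which assumes near-contiguity).
#' @param min_segment Shortest segment length in the ladder. Defaults to 8,
#'   lowered to 7 when `N <= 32` so that three lengths enter the fit for
#'   ~30-year annual records.
#' @return An object of class `hurst_fit`: `h`, `log_c`, `r_squared`,
#'   `lengths`, `mean_rs`, `n`, `reliable`, `in_range`.
#' @examples
#' rs_hurst(gen_fgn(512, hurst = 0.8, seed = 1))$h
#' @export
rs_hurst <- function(x, min_segment = NULL) {
  x <- x[is.finite(x)]
  n_tot <- length(x)
  if (is.null(min_segment)) min_segment <- if (n_tot <= 32) 7L else 8L
  out <- structure(
    list(
      h = NA_real_, log_c = NA_real_, r_squared = NA_real_,
      lengths = integer(0), mean_rs = numeric(0), n = n_tot,
      reliable = FALSE, in_range = NA
    ),
    class = "hurst_fit"
  )
  if (n_tot < 2 * min_segment) {
    return(out)
  }
  lens <- integer(0)
  n <- n_tot
  while (n >= min_segment) {
    lens <- c(lens, n)
    n <- n %/% 2L
  }
  mean_rs <- rep(NA_real_, length(lens))
  for (k in seq_along(lens)) {
    n <- lens[k]
    nseg <- n_tot %/% n
    rs <- vapply(seq_len(nseg), function(s) {
      seg <- x[((s - 1) * n + 1):(s * n)]
      m <- mean(seg)
      z <- cumsum(seg - m)
      s_n <- sqrt(mean((seg - m)^2)) # population form
      if (s_n == 0) {
        return(NA_real_)
      }
      (max(z) - min(z)) / s_n
    }, numeric(1))
    if (any(is.finite(rs))) mean_rs[k] <- mean(rs, na.rm = TRUE)
  }
  keep <- is.finite(mean_rs) & mean_rs > 0
  lens <- lens[keep]
  mean_rs <- mean_rs[keep]
  out$lengths <- lens
  out$mean_rs <- mean_rs
  if (length(lens) < 2) {
    return(out)
  }
  fit <- stats::lm(log(mean_rs) ~ log(lens))
  out$h <- unname(stats::coef(fit)[2])
  out$log_c <- unname(stats::coef(fit)[1])
  out$r_squared <- summary(fit)$r.squared
  out$reliable <- length(lens) >= 3
  out$in_range <- out$h > 0 && out$h < 1
  out
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf(
    "<hurst_fit> H = %.3f (r2 = %.3f, %d lengths%s)\n",
    x$h, x$r_squared, length(x$lengths),
    if (x$reliable) "" else ", unreliable"
  ))
  invisible(x)
}

#' @rdname rs_hurst
#' @param x A `hurst_fit` object.
#' @param ... Unused.
#' @export
tidy.hurst_fit <- function(x, ...) {
  tibble::tibble(length = x$lengths, mean_rs = x$mean_rs)
}

#' @rdname rs_hurst
#' @export
glance.hurst_fit <- function(x, ...) {
  tibble::tibble(
    h = x$h, log_c = x$log_c, r_squared = x$r_squared,
    n = x$n, n_lengths = length(x$lengths), reliable = x$reliable
  )
}

#' Six-class future-trend classification
#'
#' Combines the sign and significance of the Theil-Sen trend with the Hurst
#' exponent: a significant positive slope with persistent noise (`H > 0.5`)
#' is Positive Development (PD), with anti-persistent noise Anti-persistent
#' Positive Development (APD); a significant negative slope maps to ND /
#' AND; a nonsignificant slope maps to Sustained and Steady Development
#' (SSD) when `H > 0.5` and Undetermined Development (UD) otherwise.
#' `H = 0.5` exactly falls on the anti-persistent side, since persistence
#' is defined by `0.5 < H < 1`.
#'
#' @param slope Theil-Sen slope (vectorised).
#' @param mk_p Mann-Kendall p-value.
#' @param h Hurst exponent.
#' @param alpha Significance level.
#' @return Factor with levels PD, APD, SSD, UD, ND, AND.
#' @examples
#' classify_future_trend(0.002, 0.01, 0.7) # PD
#' @export
classify_future_trend <- function(slope, mk_p, h, alpha = 0.05) {
  sig <- !is.na(mk_p) & mk_p < alpha
  per <- h > 0.5
  cls <- dplyr::case_when(
    is.na(slope) | is.na(h) ~ NA_character_,
    sig & slope > 0 & per ~ "PD",
    sig & slope > 0 ~ "APD",
    sig & slope < 0 & per ~ "ND",
    sig & slope < 0 ~ "AND",
    per ~ "SSD",
    .default = "UD"
  )
  factor(cls, levels = c("PD", "APD", "SSD", "UD", "ND", "AND"))
}

#' Per-pixel persistence map
#'
#' Estimates the Hurst exponent of every pixel's annual series and assigns
#' the six-class future trend using a [trend_map()] result. The spatial-mean
#' H, the class shares, and (when `zones` is given) per-zone mean H are
#' attached as attributes.
#'
#' @param gsvi Annual cube tibble.
#' @param trend A [trend_map()] result for the same cube.
#' @param alpha Significance level for the trend branch.
#' @param min_segment Passed to [rs_hurst()].
#' @param zones Optional tibble with `pixel`, `zone`.
#' @return Tibble per pixel: `h`, `r_squared`, `reliable`, `future_class`;
#'   attributes `mean_h`, `class_shares`, `zonal_h`.
#' @export
persistence_map <- function(gsvi, trend, alpha = 0.05, min_segment = NULL,
                            zones = NULL) {
  m <- annual_matrix(gsvi)
  fits <- purrr::map(
    seq_len(ncol(m)),
    function(j) rs_hurst(m[, j], min_segment)
  )
  out <- tibble::tibble(
    pixel = attr(m, "pixels"),
    h = purrr::map_dbl(fits, "h"),
    r_squared = purrr::map_dbl(fits, "r_squared"),
    reliable = purrr::map_lgl(fits, "reliable")
  )
  out <- dplyr::left_join(
    out, trend[, c("pixel", "slope", "mk_p")],
    by = "pixel"
  )
  out$future_class <- classify_future_trend(
    out$slope, out$mk_p, out$h,
    alpha
  )
  out <- dplyr::left_join(pixel_meta(gsvi), out, by = "pixel")
  cnt <- table(out$future_class)
  attr(out, "mean_h") <- mean(out$h, na.rm = TRUE)
  attr(out, "class_shares") <- tibble::tibble(
    future_class = names(cnt), n = as.integer(cnt),
    share = as.numeric(cnt) / sum(cnt) * 100
  )
  if (!is.null(zones)) {
    attr(out, "zonal_h") <- out |>
      dplyr::inner_join(zones[, c("pixel", "zone")], by = "pixel") |>
      dplyr::summarise(mean_h = mean(.data$h, na.rm = TRUE), .by = "zone")
  }
  out
}
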