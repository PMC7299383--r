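# Pettitt single change-point detection.

#' Pettitt change-point test
#'
#' Rank-based nonparametric test for a single change point. With ranks `R_i`
#' (midranks for ties) of the `N` values, `U_t = 2 sum_{i<=t} R_i - t(N+1)`,
#' which for tie-free series equals the Mann-Whitney-type double sum
#' `sum_{i<=t} sum_{j>t} sgn(x_i - x_j)` (the cumulated-`V` form
#' `V_i = N + 1 - 2 R_i` is its negation; the magnitude is identical). The
#' statistic is `K_N = max_t |U_t|` over `t = 1 .. N-1` and the approximate
#' two-sided significance is `p = 2 exp(-6 K_N^2 / (N^3 + N^2))` (clamped to
#' 1 for reporting).
#'
#' The change index `t` is the `argmax |U_i|` (earliest on ties), i.e. the
#' last index of the pre-change regime; the first year of the new regime is
#' `t + 1`.
#'
#' @param x Numeric series; `NA`s are dropped (positions compress).
#' @param alpha Significance level.
#' @return An object of class `pettitt_test`: `t_index`, `k`, `p`,
#'   `significant`, `n`, `u` (the U trajectory).
#' @examples
#' pettitt_test(c(rnorm(15), rnorm(16, mean = 3)))
#' @export
pettitt_test <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) rlang::abort("Pettitt test needs at least 8 valid points")
  r <- rank(x) # midranks on ties
  # Pettitt's U_t = 2 * sum_{i<=t} R_i - t(N+1); equal to the sign double
  # sum. |U| (hence K and the change index) is convention-independent.
  u <- cumsum(2 * r - (n + 1))
  absu <- abs(u[seq_len(n - 1)])
  k <- max(absu)
  t_index <- which.max(absu) # earliest maximiser
  p_raw <- 2 * exp(-6 * k^2 / (n^3 + n^2))
  structure(
    list(
      t_index = t_index, k = k, p = min(p_raw, 1),
      significant = p_raw < alpha, n = n, u = u,
      ties = anyDuplicated(x) > 0, alpha = alpha
    ),
    class = "pettitt_test"
  )
}

#' @export
print.pettitt_test <- function(x, ...) {
  cat(sprintf(
    "<pettitt_test> K = %g at index %d (n = %d), p = %.4g%s\n",
    x$k, x$t_index, x$n, x$p,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' @rdname pettitt_test
#' @param ... Unused.
#' @export
tidy.pettitt_test <- function(x, ...) {
  tibble::tibble(index = seq_len(x$n), u = x$u)
}

#' @rdname pettitt_test
#' @export
glance.pettitt_test <- function(x, ...) {
  tibble::tibble(
    t_index = x$t_index, k = x$k, p = x$p,
    significant = x$significant, n = x$n
  )
}

#' Per-pixel change-point map
#'
#' Runs the Pettitt test on every pixel's annual series; pixels without a
#' significant change point get `NA` as change year. By convention the
#' reported change year is the first year of the new regime
#' (`convention = "first_new"`); `"last_old"` reports the last pre-change
#' year instead.
#'
#' @param gsvi Annual cube tibble.
#' @param alpha Significance level.
#' @param convention `"first_new"` or `"last_old"`.
#' @param min_years Minimum valid years per pixel.
#' @return Tibble per pixel: `change_year`, `k`, `p`, `significant`;
#'   `attr(, "histogram")` is the change-year tally over significant
#'   pixels.
#' @export
changepoint_map <- function(gsvi, alpha = 0.05,
                            convention = c("first_new", "last_old"),
                            min_years = 8) {
  convention <- match.arg(convention)
  m <- annual_matrix(gsvi)
  years <- attr(m, "years")
  res <- purrr::map(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    ok <- is.finite(y)
    if (sum(ok) < min_years) {
      return(tibble::tibble(
        change_year = NA_integer_, k = NA_real_,
        p = NA_real_, significant = NA
      ))
    }
    pt <- pettitt_test(y[ok], alpha)
    yrs <- years[ok]
    cy <- if (convention == "first_new") {
      yrs[min(pt$t_index + 1, length(yrs))]
    } else {
      yrs[pt$t_index]
    }
    tibble::tibble(
      change_year = if (pt$significant) as.integer(cy) else NA_integer_,
      k = pt$k, p = pt$p, significant = pt$significant
    )
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(tibble::tibble(pixel = attr(m, "pixels")), res)
  out <- dplyr::left_join(pixel_meta(gsvi), out, by = "pixel")
  hist <- out |>
    dplyr::filter(!is.na(.data$change_year)) |>
    dplyr::count(.data$change_year, name = "n_pixels")
  attr(out, "histogram") <- hist
  attr(out, "alpha") <- alpha
  out
}
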