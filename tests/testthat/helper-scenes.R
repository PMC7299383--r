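# Fixture builders shared across the suite. Everything is generated in code.

# Annual cube tibble from a years x pixels matrix on a default grid.
annual_cube_from_matrix <- function(m, start_year = 1982, res = 0.1) {
  ny <- nrow(m)
  np <- ncol(m)
  nr <- max(1, floor(sqrt(np)))
  nc <- ceiling(np / nr)
  grid <- make_grid(nr, nc, res = res)[seq_len(np), ]
  tibble::tibble(
    pixel = rep(grid$pixel, each = ny),
    row = rep(grid$row, each = ny),
    col = rep(grid$col, each = ny),
    lon = rep(grid$lon, each = ny),
    lat = rep(grid$lat, each = ny),
    year = rep(start_year + seq_len(ny) - 1, times = np),
    value = as.vector(m),
    valid = is.finite(as.vector(m))
  )
}

# Monthly climate cube from a function of (year index, month).
monthly_cube <- function(np, ny, f, start_year = 1982) {
  nr <- max(1, floor(sqrt(np)))
  nc <- ceiling(np / nr)
  grid <- make_grid(nr, nc)[seq_len(np), ]
  g <- tidyr::expand_grid(
    pixel = grid$pixel,
    yi = seq_len(ny), month = 1:12
  )
  dplyr::left_join(g, grid, by = "pixel") |>
    dplyr::mutate(
      year = start_year + .data$yi - 1,
      value = f(.data$yi, .data$month),
      valid = TRUE
    ) |>
    dplyr::select(
      "pixel", "row", "col", "lon", "lat",
      "year", "month", "value", "valid"
    )
}

# Savitzky-Golay convolution coefficients from the normal equations:
# projection of the window onto polynomials of degree `polyorder`,
# evaluated at offset `at` from the window center.
sg_coefficients <- function(window, polyorder, at = 0) {
  h <- (window - 1) / 2
  a <- outer(-h:h, 0:polyorder, "^")
  proj <- a %*% solve(crossprod(a), t(a))
  proj[at + h + 1, ]
}

# Pettitt U trajectory by the brute-force sign double sum:
# U_t = sum_{i<=t} sum_{j>t} sgn(x_i - x_j).
pettitt_u_bruteforce <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    s <- 0
    for (i in seq_len(t)) {
      for (j in seq_len(n)[-seq_len(t)]) {
        s <- s + sign(x[i] - x[j])
      }
    }
    s
  }, numeric(1))
}

# LMG for two predictors by explicit enumeration of both orderings,
# each increment from nested lm() fits.
lmg_two_orderings <- function(y, x1, x2) {
  r2 <- function(fit) summary(fit)$r.squared
  r2_1 <- r2(stats::lm(y ~ x1))
  r2_2 <- r2(stats::lm(y ~ x2))
  r2_12 <- r2(stats::lm(y ~ x1 + x2))
  # ordering (1,2): increments r2_1, r2_12 - r2_1
  # ordering (2,1): increments r2_12 - r2_2, r2_2
  share1 <- mean(c(r2_1, r2_12 - r2_2))
  share2 <- mean(c(r2_2, r2_12 - r2_1))
  c(share1 = share1, share2 = share2, r2 = r2_12)
}
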