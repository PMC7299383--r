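test_that("seasonal windows aggregate temperature means and
           precipitation sums", {
  temp <- monthly_cube(4, 3, function(yi, m) 5)
  precip <- monthly_cube(4, 3, function(yi, m) 10)
  sc <- seasonal_climate(temp, precip)
  expect_equal(unique(sc$pre_t), 5)
  expect_equal(unique(sc$gs_t), 5)
  expect_equal(unique(sc$post_t), 5)
  expect_equal(unique(sc$pre_p), 40) # 4 months x 10
  expect_equal(unique(sc$gs_p), 50) # 5 months x 10
  expect_equal(unique(sc$post_p), 30) # 3 months x 10
})

test_that("window summaries are invariant to permuting months within a
           window and drop incomplete windows", {
  set.seed(22)
  vals <- matrix(rnorm(12 * 2, 10, 3), 12, 2)
  temp <- monthly_cube(1, 2, function(yi, m) vals[cbind(m, yi)])
  # permute May-Sep values within each year
  perm <- c(5, 9, 6, 8, 7)
  temp2 <- temp
  for (y in unique(temp$year)) {
    sel <- temp$year == y & temp$month %in% 5:9
    temp2$value[sel] <- temp$value[sel][match(perm, 5:9)]
  }
  precip <- monthly_cube(1, 2, function(yi, m) 1)
  expect_equal(
    seasonal_climate(temp2, precip)$gs_t,
    seasonal_climate(temp, precip)$gs_t
  )
  # invalid month kills the window
  temp3 <- temp
  temp3$valid[temp3$month == 6] <- FALSE
  sc3 <- seasonal_climate(temp3, precip)
  expect_true(all(is.na(sc3$gs_t)))
  expect_false(anyNA(sc3$pre_t))
})

test_that("Spearman maps hit +/-1 on monotone couplings and match the
           rank-then-Pearson oracle", {
  set.seed(23)
  m <- matrix(0.3 + rnorm(31 * 4, 0, 0.05), 31, 4)
  cube <- annual_cube_from_matrix(m)
  clim <- tibble::tibble(
    pixel = rep(1:4, each = 31),
    year = rep(1982:2012, 4),
    gs_t = as.vector(m), # driver equal to GSVI
    gs_p = -as.vector(m)
  )
  r_t <- spearman_map(cube, clim, "gs_t")
  expect_equal(r_t$r, rep(1, 4))
  r_p <- spearman_map(cube, clim, "gs_p")
  expect_equal(r_p$r, rep(-1, 4))
  shares <- attr(r_t, "sign_shares")
  expect_equal(shares$share[shares$sign == "positive"], 100)
  # oracle: Pearson correlation of midranks
  clim$gs_t <- rnorm(124)
  r <- spearman_map(cube, clim, "gs_t")
  for (p in 1:4) {
    x <- m[, p]
    y <- clim$gs_t[clim$pixel == p]
    expect_equal(r$r[r$pixel == p], cor(rank(x), rank(y)),
      tolerance = 1e-12
    )
  }
  # monotone-transform invariance
  clim2 <- clim
  clim2$gs_t <- exp(clim$gs_t)
  expect_equal(spearman_map(cube, clim2, "gs_t")$r, r$r)
})

test_that("LMG raw shares sum to R2 and match the ordering-enumeration
           oracle", {
  set.seed(24)
  for (rep in 1:20) {
    n <- 31
    x1 <- rnorm(n)
    x2 <- 0.6 * x1 + rnorm(n, 0, 0.8) # correlated predictors
    y <- 0.5 * x1 - 0.3 * x2 + rnorm(n, 0, 0.7)
    res <- lmg_importance(y, cbind(a = x1, b = x2))
    orc <- lmg_two_orderings(y, x1, x2)
    expect_equal(sum(res$raw), res$r_squared, tolerance = 1e-10)
    expect_equal(unname(res$raw["a"]), unname(orc["share1"]),
      tolerance = 1e-10
    )
    expect_equal(unname(res$raw["b"]), unname(orc["share2"]),
      tolerance = 1e-10
    )
    expect_equal(sum(res$normalized), 100, tolerance = 1e-10)
    expect_true(all(res$raw >= -1e-12))
  }
})

test_that("orthogonal predictors get their own single-predictor R2 and
           degenerate inputs are flagged", {
  n <- 32
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4) # exactly orthogonal to x1
  set.seed(25)
  y <- x1 + 2 * x2 + rnorm(n, 0, 0.5)
  res <- lmg_importance(y, cbind(a = x1, b = x2))
  r2a <- summary(lm(y ~ x1))$r.squared
  r2b <- summary(lm(y ~ x2))$r.squared
  expect_equal(unname(res$raw["a"]), r2a, tolerance = 1e-10)
  expect_equal(unname(res$raw["b"]), r2b, tolerance = 1e-10)
  # collinear predictors flagged
  col <- lmg_importance(y, cbind(a = x1, b = 2 * x1))
  expect_false(col$ok)
  # pure-temperature signal
  pure <- lmg_contributions(3 * x1, x1, x2)
  expect_equal(pure$contribution_t, 100, tolerance = 1e-8)
})

test_that("six-predictor LMG still sums to R2 and stays nonneg-normalized", {
  set.seed(26)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 2] <- x[, 1] * 0.5 + x[, 2]
  y <- x %*% c(1, 0.5, 0, -0.3, 0.2, 0) + rnorm(n)
  res <- lmg_importance(y, x)
  expect_equal(sum(res$raw), res$r_squared, tolerance = 1e-10)
  expect_equal(sum(res$normalized), 100, tolerance = 1e-8)
})

test_that("attribution maps recover constructed 100% and 75% temperature
           contributions", {
  set.seed(27)
  sp <- synthetic_spec(5, 5,
    years = 31, baseline = 0.4, noise_sd = 0,
    seasonal_amplitude = 0.1, seed = 28
  )
  # beta_p = 0: everything from temperature
  cl <- gen_climate_cubes(sp, beta_t = 0.02, beta_p = 0)
  sc <- gen_ndvi_cube(sp, climate = cl)
  gsvi <- composite_gsvi(sc$cube)
  clim <- seasonal_climate(
    regrid_nearest(cl$temp, pixel_meta(gsvi)),
    regrid_nearest(cl$precip, pixel_meta(gsvi))
  )
  am <- attribution_map(gsvi, clim, "growing")
  # precipitation only picks up a chance-correlation share of order 1/n
  expect_gt(median(am$contribution_t, na.rm = TRUE), 95)
  expect_true(all(am$contribution_t > 85, na.rm = TRUE))
  expect_equal(am$contribution_t + am$contribution_p,
    rep(100, nrow(am)),
    tolerance = 1e-8
  )
})
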