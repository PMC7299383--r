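test_that("Theil-Sen equals the brute-force pairwise-slope median", {
  expect_equal(theil_sen(c(1, 2, 3, 4, 5)), 1)
  expect_equal(theil_sen(rep(2, 8)), 0)
  set.seed(42)
  for (r in 1:25) {
    y <- rnorm(31)
    slopes <- c()
    for (j in 2:31) {
      for (i in 1:(j - 1)) {
        slopes <- c(slopes, (y[j] - y[i]) / (j - i))
      }
    }
    expect_length(slopes, 465)
    s <- sort(slopes) # midpoint-average median, independently coded
    med <- (s[232] + s[234 - 1]) / 2
    med <- if (length(s) %% 2 == 1) s[(length(s) + 1) / 2] else med
    expect_equal(theil_sen(y), med, tolerance = 1e-12)
  }
})

test_that("Theil-Sen is shift-invariant, scale-equivariant and robust", {
  set.seed(1)
  y <- cumsum(rnorm(20))
  expect_equal(theil_sen(y + 100), theil_sen(y))
  expect_equal(theil_sen(3 * y), 3 * theil_sen(y))
  # one gross outlier moves Theil-Sen less than OLS
  clean <- 0.1 * (1:31) + rnorm(31, 0, 0.1)
  dirty <- clean
  dirty[29] <- dirty[29] + 50 # off-center outlier has OLS leverage
  ts_shift <- abs(theil_sen(dirty) - theil_sen(clean))
  ols <- function(v) unname(coef(lm(v ~ seq_along(v)))[2])
  ols_shift <- abs(ols(dirty) - ols(clean))
  expect_lt(ts_shift, ols_shift)
  expect_true(is.na(theil_sen(c(1, NA, NA))))
})

test_that("Mann-Kendall S, antisymmetry and tie degeneracy behave", {
  expect_equal(mann_kendall(1:10)$s, 45)
  set.seed(2)
  for (r in 1:10) {
    y <- rnorm(15)
    a <- mann_kendall(y)
    b <- mann_kendall(rev(y))
    expect_equal(b$s, -a$s)
    expect_equal(b$p, a$p)
  }
  deg <- mann_kendall(rep(1, 10))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("Mann-Kendall p matches the continuity-corrected normal
           approximation of cor.test", {
  set.seed(3)
  for (r in 1:20) {
    y <- rnorm(31)
    ours <- mann_kendall(y)
    ct <- suppressWarnings(cor.test(seq_along(y), y,
      method = "kendall", exact = FALSE, continuity = TRUE
    ))
    expect_equal(ours$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Kendall is roughly calibrated under the null", {
  set.seed(4)
  n_rep <- 1500
  rej <- vapply(seq_len(n_rep), function(i) {
    mann_kendall(rnorm(31))$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.005)
})

test_that("CV is the sample-sd relative dispersion in percent", {
  expect_equal(cv_percent(rep(3, 10)), 0)
  y <- c(9, 10, 11) # mean 10, sd 1
  expect_equal(cv_percent(y), 10)
  set.seed(5)
  z <- rexp(40) + 1
  expect_equal(cv_percent(z), 100 * sd(z) / mean(z))
  expect_true(is.na(cv_percent(c(-1, 1))))
})

test_that("trend_map partitions constructed slopes exactly", {
  ny <- 31
  np <- 40
  m <- matrix(0, ny, np)
  for (j in 1:20) m[, j] <- 0.3 + 0.004 * (1:ny)
  for (j in 21:40) m[, j] <- 0.5 - 0.004 * (1:ny)
  tm <- trend_map(annual_cube_from_matrix(m))
  expect_equal(sum(tm$class == "positive"), 20)
  expect_equal(sum(tm$class == "negative"), 20)
  sm <- attr(tm, "summary")
  expect_equal(sum(sm$n), 40)
  expect_equal(sum(sm$share), 100)
})

test_that("decade comparison reproduces the Welch formula and its
           antisymmetry", {
  set.seed(6)
  m <- matrix(0.3 + rnorm(31 * 9, 0, 0.02), 31, 9)
  cube <- annual_cube_from_matrix(m)
  wins <- list(a = 1982:1991, b = 1992:2001, c = 2002:2011)
  dc <- decade_compare(cube, wins)
  expect_equal(nrow(dc$tests), 3)
  # hand Welch t for the first pair from the spatial-mean series
  sm <- dc$series
  x1 <- sm$gsvi[sm$window == "a"]
  x2 <- sm$gsvi[sm$window == "b"]
  t_hand <- (mean(x1) - mean(x2)) /
    sqrt(var(x1) / length(x1) + var(x2) / length(x2))
  expect_equal(dc$tests$t[dc$tests$window_a == "a" &
    dc$tests$window_b == "b"], t_hand)
  # swapped windows flip the sign
  dc2 <- decade_compare(cube, list(b = 1992:2001, a = 1982:1991))
  expect_equal(dc2$tests$t, -dc$tests$t[1])
  expect_equal(dc2$tests$p, dc$tests$p[1])
  expect_error(decade_compare(cube, list(a = 1982:1991, b = 1990:1999)),
    "overlap")
})

test_that("identical decade windows give t = 0, p = 1", {
  m <- matrix(rep(c(0.3, 0.31), length.out = 31 * 4), 31, 4)
  cube <- annual_cube_from_matrix(m)
  # two windows with identical value patterns by construction
  cube20 <- dplyr::filter(cube, year <= 2001)
  dc <- decade_compare(cube20, list(a = 1982:1991, b = 1992:2001))
  expect_equal(dc$tests$t, 0, tolerance = 1e-8)
  expect_equal(dc$tests$p, 1, tolerance = 1e-8)
})

test_that("zonal summaries reduce to global statistics for one zone and
           split opposite trends", {
  ny <- 31
  m <- cbind(
    sapply(1:10, function(j) 0.3 + 0.004 * (1:ny)),
    sapply(1:10, function(j) 0.5 - 0.004 * (1:ny))
  )
  cube <- annual_cube_from_matrix(m)
  tm <- trend_map(cube)
  one <- zonal_summary(cube, tm,
    tibble::tibble(pixel = 1:20, zone = "all"))
  glob <- cube |>
    dplyr::summarise(g = mean(value), .by = year)
  expect_equal(one$mean_gsvi, mean(glob$g))
  expect_equal(one$n_pixels, 20)
  two <- zonal_summary(cube, tm,
    tibble::tibble(pixel = 1:20, zone = rep(c("up", "down"), each = 10)))
  expect_gt(two$slope_full[two$zone == "up"], 0)
  expect_lt(two$slope_full[two$zone == "down"], 0)
  expect_equal(sum(two$n_sig_positive, two$n_sig_negative), 20)
})
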