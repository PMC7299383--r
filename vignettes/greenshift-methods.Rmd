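---
title: "Methods: trend, persistence and attribution analysis of growing-season vegetation cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend, persistence and attribution analysis of growing-season vegetation cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenshift)
library(dplyr)
```

## The analysis problem

Multi-decade satellite greenness records (NDVI at a semimonthly cadence on a
regular grid) are the standard evidence base for asking whether vegetation in
a region is greening or browning, whether observed tendencies will persist,
when abrupt shifts happened, and how much of the interannual variation is
attributable to temperature versus precipitation. greenshift implements that
full per-pixel workflow on tidy "cube" tibbles — one row per pixel-time cell —
so every stage composes with dplyr verbs and returns a tibble.

The annual unit of analysis is the growing-season vegetation index (GSVI):
the mean of the valid May–September NDVI observations of a pixel-year. Using
a within-season mean deliberately ignores off-season observations, which in
cold-region records are dominated by snow and low-sun artifacts.

## Preprocessing

Raw semimonthly cubes pass through four stages:

1. **Quality masking** (`apply_quality_mask()`): observations whose quality
   flag is outside the reliable set (default `{1, 2, 3, 5}`) are invalidated.
   The flag semantics are product-specific, so the keep-set is a plain
   argument rather than a hard-coded rule.
2. **Savitzky–Golay smoothing** (`savgol_smooth()`, `smooth_cube()`): a
   7-point local least-squares polynomial filter (order 2 by default —
   the common choice for NDVI phenology, and the lowest order that tracks
   seasonal curvature without chasing noise). Internal gaps of up to 3 steps
   (`max_gap`) are linearly interpolated before filtering and returned as
   valid; longer gaps stay invalid. The filter reproduces polynomials up to
   its order exactly, which the test suite asserts against coefficients
   derived independently from the normal equations.
3. **Barren filtering** (`mask_barren()`): pixels whose all-record mean NDVI
   is strictly below 0.05 are removed entirely; trend statistics on barren
   ground are noise. The comparison is strict, so a pixel at exactly 0.05 is
   retained.
4. **Compositing** (`composite_gsvi()`): a pixel-year needs at least 7 of
   its 10 growing-season slots valid (default `min_obs = 7`) to yield a
   GSVI value — tolerant of flag dropouts, but never letting one or two
   observations define a season.

Monthly climate cubes on a coarser grid are brought to the vegetation grid
by nearest-neighbour copying (`regrid_nearest()`; values are never
interpolated) and sub-monthly records are aggregated to calendar months
(`aggregate_monthly()`: means for temperature, sums for precipitation).

## Trend and variability statistics

For each pixel's annual GSVI series `y_1..y_n` (time measured in integer
year index, so slopes are per year):

* **Theil–Sen slope** (`theil_sen()`): the median of all `n(n-1)/2` pairwise
  slopes `(y_i - y_j)/(i - j)`, robust to outliers; even counts use the
  midpoint-average median.
* **Mann–Kendall test** (`mann_kendall()`): `S = sum_{i<j} sgn(y_j - y_i)`
  with the tie-corrected variance
  `[n(n-1)(2n+5) - sum_t t(t-1)(2t+5)]/18` and a ±1 continuity correction in
  the normal approximation. An all-tied series has zero variance and is
  reported as `p = 1` with a degeneracy flag rather than an error.
* **Coefficient of variation** (`cv_percent()`): `100 * sd / mean` with the
  sample (n−1) standard deviation. The denominator convention is not
  universal; the sample form is chosen because zonal CV values are compared
  across series of equal, moderate length.

`trend_map()` applies all three per pixel and partitions pixels into
significant-positive / significant-negative / nonsignificant classes at
`alpha = 0.05`. `decade_compare()` compares the spatial-mean GSVI of
non-overlapping 10-year windows with Welch's unequal-variance t-test
(degenerate zero-variance windows short-circuit to `t = 0, p = 1` when
equal). `zonal_summary()` aggregates the same statistics over an ecoregion
label raster.

## Persistence: rescaled-range Hurst exponent

`rs_hurst()` implements classical R/S analysis. The series of length `N` is
divided into disjoint segments of length `n = N, floor(N/2), floor(N/4), ...`;
per segment the range of cumulative mean-deviations is divided by the
population (1/n) standard deviation; `R/S` is averaged over segments of the
same length, and `H` is the slope of `log(R/S)` against `log(n)`.

Numerical choices:

* The ladder stops at `min_segment = 8`, lowered to 7 when `N <= 32` so a
  31-year record still contributes three lengths `{31, 15, 7}` to the fit.
  With fewer than three usable lengths the estimate is flagged unreliable.
* Segments with zero variance are excluded; a constant series yields `NA`
  with `reliable = FALSE`, never a silent number.
* Trailing observations that do not fill a segment are dropped (the
  classical recipe), so non-dyadic lengths are handled deterministically.
* R/S has a well-known upward small-sample bias: on exact fractional
  Gaussian noise at `N = 1024` the mean estimate is within ±0.09 of truth
  for `H ∈ {0.3, 0.5, 0.8}` (measured over 200 replicates in the acceptance
  suite), while at `N = 31` white noise averages `H ≈ 0.6` with spread ±0.15.
  Pixel-level `H` values from 31-year records are therefore read
  comparatively (strata orderings, class shares), not as calibrated
  absolute memory estimates.

`classify_future_trend()` crosses trend sign/significance with `H`:
PD / APD (significant greening, persistent / anti-persistent), ND / AND
(significant browning), SSD / UD (no significant trend). `H = 0.5` exactly
is assigned to the anti-persistent branch because persistence is defined by
`0.5 < H < 1`; estimates outside (0, 1) keep their numeric value, are
flagged, and classify by the 0.5 threshold. The six classes partition every
finite input, which is property-tested.

## Change points: Pettitt test

`pettitt_test()` uses the rank form `U_t = 2 sum_{i<=t} R_i - t(N+1)`
(midranks on ties), which for tie-free data equals the sign double sum
`sum_{i<=t} sum_{j>t} sgn(x_i - x_j)` — the suite asserts that equality
against a brute-force double loop. The statistic is `K_N = max |U_t|` over
`t = 1..N-1` and the approximate significance is
`p = 2 exp(-6 K_N^2 / (N^3 + N^2))`, clamped to 1 for reporting. One
widely-reprinted typographic corruption of this formula (an additive rather
than divisive `N^3 + N^2` term) is deliberately not followed; the
exponential form above is the one consistent with the original test and is
validated here by its null calibration (empirical size ≤ nominal 0.05 over
10,000 white-noise series — the approximation is known to be conservative).

The change index `t` is the last index of the pre-change regime;
`changepoint_map()` reports the calendar year of `t + 1` (first year of the
new regime) by default, with a `convention` flag for the other reading,
since printed change-year maps are ambiguous on this point. Only the single
most significant change point is sought; no recursive segmentation.

## Spatiotemporal structure: z-scores, Hovmöller, EOF

`zscore_anomaly()` standardizes each pixel by its own temporal mean and
sample sd (zero-variance pixels are invalidated). `hovmoller()` averages
the z-cube over half-open latitude (or longitude) bins — default 0.25°,
pixels assigned by center coordinate — giving the classic time-latitude
section.

`eof_decompose()` performs covariance (not correlation) EOF analysis:
each pixel series is centered by its temporal mean, no variance
normalization and no cos(latitude) area weighting (exposed as future
options through the centered flag; the uncentered variant trivially
inflates mode 1 with the climatological mean pattern and is available with
`center = FALSE`). Only pixels with complete series enter the space × time
matrix, which is decomposed by SVD; mode `k` explains
`sigma_k^2 / sum sigma^2` of the variance. Because SVD signs are arbitrary,
each mode is scaled so that its largest-magnitude spatial loading is
positive, making results deterministic across platforms. `eof_reconstruct()`
inverts the decomposition (exactly, when all modes are kept).

## Climate attribution: Spearman and LMG

The analysis year is split into preseason (Jan–Apr), growing season
(May–Sep) and postseason (Oct–Dec); `seasonal_climate()` produces window
means for temperature (PreT, GST, PostT) and window sums for precipitation
(PreP, GSP, PostP). A window missing any month for a pixel-year is invalid.

`spearman_map()` reports per-pixel rank correlations of GSVI with one
driver plus the shares of positively and negatively correlated pixels;
significance is not mapped because sign shares, not p-values, are the
interpretive quantity at pixel scale.

`lmg_importance()` decomposes the R² of an OLS fit into per-predictor
contributions by averaging each predictor's sequential R² increment over
all orderings of entry (Lindeman–Merenda–Gold). It is implemented by
subset-R² enumeration, exact for up to ~6 predictors; for the standard
two-predictor case the closed form
`share_T = [R²(T) + R²(T,P) − R²(P)]/2` is the independent oracle in the
tests. Raw shares are nonnegative for two predictors and sum exactly to the
full-model R²; reported contributions are normalized to sum to 100%.
`attribution_map()` fits one two-predictor model per seasonal window
(matched temperature/precipitation pairs) rather than one six-predictor
model — contribution maps come in matched T/P pairs per window, and the
per-window model keeps each map interpretable; the six-predictor
decomposition remains available directly through `lmg_importance()`.

## The synthetic-data generator

`synthetic_spec()` + `gen_ndvi_cube()` + `gen_climate_cubes()` produce
scenes in which every quantity the pipeline estimates is known by
construction:

* **Interannual noise** is exact-covariance fractional Gaussian noise
  (`gen_fgn()`, Davies–Harte circulant embedding; `fgn_acov()` is the
  closed-form autocovariance that the generator's output is tested
  against). Exactness matters: an approximate generator would confound
  generator bias with estimator bias in the Hurst-recovery checks. The fGn
  perturbs the *annual* level (constant within a year), because it models
  memory in the growing-season state, not sub-seasonal weather.
* **Seasonal cycle**: a raised cosine over May–September, centred to zero
  mean within the window, so the GSVI composite recovers the annual level
  exactly and is insensitive to cycle phase.
* **Trends and steps** are linear per-pixel ramps and single steps confined
  to year indices `4..N-3`, so a change-point test always has support on
  both sides.
* **Climate coupling**: seasonal-window anomalies are drawn independently
  per window and year; GSVI adds `beta_T * GST_anom + beta_P * GSP_anom`,
  so the true temperature contribution is
  `beta_T² var(GST) / (beta_T² var(GST) + beta_P² var(GSP))` in closed form.
* **Degradations**: quality-flag dropouts at a configurable rate, a
  configurable fraction of sub-threshold (barren) pixels, and clipping to
  the physical NDVI range [−0.2, 1] (clip counts are recorded, since heavy
  clipping biases extreme-noise scenarios).

All randomness flows from the single spec seed; equal specs reproduce
bit-identical scenes.

What the generator does **not** emulate: sensor-change artifacts and orbital
drift, spatially correlated noise fields, cloud-contamination streaks with
realistic temporal autocorrelation, realistic topographic structure, or
mixed-pixel effects. Passing recovery tests on these scenes therefore
demonstrates the correctness and calibration of the estimators, not the
field accuracy of conclusions drawn from any particular satellite product.

## Verification problem sizes

The test and acceptance suites use: 200 length-31 series for the Theil–Sen
oracle; 10,000 white-noise series (n = 31) for Mann–Kendall and Pettitt
null calibration; 1,000 replicates of a 2σ midpoint step for Pettitt power;
200 replicates of length-1024 exact fGn at H ∈ {0.3, 0.5, 0.8} for Hurst
recovery; 500 synthetic pixels (n = 31) with a true 75% temperature
contribution for LMG recovery; and one 50 × 50 × 31-year scene with trend,
change-point and Hurst strata for the end-to-end run. These sizes were
chosen so Monte-Carlo error is small relative to each tolerance.

## Known limitations

* R/S Hurst estimates from ~30-year series are high-variance and biased
  toward 0.5–0.6; class shares built on them inherit that softness.
* The Pettitt p approximation is conservative at small n; empirical size
  at n = 31 runs near 0.02–0.03 at nominal 0.05.
* Mann–Kendall is applied without prewhitening, so serially correlated
  (high-H) series reject more often than nominal — a property of the
  classical method chain, preserved deliberately.
* No cartographic projection handling: grids are plain lon/lat tibbles and
  inputs are assumed co-registered up to resolution.
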