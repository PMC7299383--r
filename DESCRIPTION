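Package: greenshift
Title: Pixel-Wise Trend, Persistence and Attribution Analysis of Growing-Season Vegetation Index Cubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for spatiotemporal analysis of gridded growing-season
    vegetation index (GSVI) time series: quality masking, Savitzky-Golay
    smoothing and growing-season compositing of semimonthly NDVI cubes;
    per-pixel Theil-Sen slopes with Mann-Kendall significance and coefficients
    of variation; rescaled-range (R/S) Hurst exponents with a six-class
    future-trend classification; Pettitt change-point detection; standardized
    anomalies, Hovmoller sections and EOF decomposition; and Spearman
    correlation plus Lindeman-Merenda-Gold (LMG) relative-importance
    attribution of temperature versus precipitation effects on greenness.
    A synthetic-data generator with exact-covariance fractional Gaussian noise
    provides ground truth for every stage, so the full pipeline is testable
    without satellite or reanalysis downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    zoo,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr,
    jsonlite,
    withr
Config/testthat/edition: 3
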