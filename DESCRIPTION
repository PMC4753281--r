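Package: thermovar
Title: Disentangling Mortality Associations of Mean Temperature and
    Temperature Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the association of daily mortality with
    mean daily temperature and with inter- and intraday temperature
    variation from city-level time series. Implements distributed lag
    non-linear models through a tensor-product cross-basis (quadratic
    B-spline over temperature, natural cubic spline over 0-21 day lags),
    a two-step minimum-mortality-temperature procedure, four
    variation indices defined relative to the minimum mortality
    temperature, quasi-Poisson estimation with Pearson-dispersion scaled
    covariance, cumulative risk summaries with Wald intervals, a
    sensitivity-analysis suite, and a synthetic daily-series generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
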