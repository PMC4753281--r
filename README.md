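# thermovar

Does temperature *change* kill, or is it just how hot or cold it is?
`thermovar` implements a modelling strategy for disentangling the
mortality association of mean daily temperature — non-linear and lagged
over three weeks — from the associations of inter- and intraday
temperature variation, for epidemiologists working with city-level daily
time series of death counts and weather.

## The model

For daily deaths with expectation μ_t, the package fits the
overdispersed Poisson model

    log(μ_t) = α + s(x_t, ℓ; β) + γ·Δx_t^b,inc + δ·Δx_t^b,dec
             + φ·Δx_t^w,hot + ϑ·Δx_t^w,cold + Σ_i f(z_ti; θ)

where

- `s(x, ℓ; β)` is a distributed lag non-linear surface of mean daily
  temperature, built as a cross-basis: a quadratic B-spline over
  temperature (3 internal knots at the 10th/75th/90th percentiles)
  crossed with a natural cubic spline over lags 0–21 days (3 knots
  equally spaced on the log-lag scale, plus an intercept);
- the four variation indices are defined relative to the minimum
  mortality temperature (MMT), the temperature at which the overall
  cumulative curve is lowest:
  - interday increase  `Δ^b,inc_t = max[x_t − max(x_{t−1}, MMT), 0]`
  - interday decrease  `Δ^b,dec_t = max[min(x_{t−1}, MMT) − x_t, 0]`
  - DTR on hot days    `Δ^w,hot_t = x^max_t − x^min_t` if `x_t > MMT`, else 0
  - DTR on cold days   `Δ^w,cold_t = x^max_t − x^min_t` if `x_t < MMT`, else 0
- `f(z; θ)` are a natural cubic trend spline (8 df per study year),
  day-of-week indicators, and optionally a 3-df spline of relative
  humidity.

Estimation is two-step: first a model with only the cross-basis is fit
and the MMT located as the argmin of its lag-cumulated curve over the
1st–99th percentile range of temperature; then the four indices are
computed from that MMT and added linearly (lag 0). Fitting is
quasi-Poisson: Poisson maximum likelihood via IRLS with covariance
scaled by the Pearson dispersion. Results are reported as relative risks:
heat and cold at the 99th/1st temperature percentiles versus the MMT,
and each variation index per its median nonzero change, all with Wald
95% intervals.

A synthetic-data module generates daily series with known ground truth
(seasonal AR(1) temperature, a diurnal-range process, a V-shaped
lag-distributed temperature effect, linear index effects, configurable
overdispersion), so every stage of the pipeline is testable without any
data download.

## Worked example

```r
library(thermovar)

series <- generate_city(synth_config(n_years = 5, seed = 42))
res <- run_city_analysis(series)
res
#> <city_analysis> [synthetic] 1805 obs, MMT 19.5 °C (93rd pct), dispersion 1.33
#> # A tibble: 6 × 5
#>   label            rr ci_low ci_high contrast
#>   <chr>         <dbl>  <dbl>   <dbl> <chr>
#> 1 heat           1.10  0.996    1.22 99th pct (22.4 °C) vs MMT (19.5 °C)
#> 2 cold           1.25  1.08     1.45 1st pct (-0.5 °C) vs MMT (19.5 °C)
#> 3 interday_inc   1.01  0.984    1.04 per median nonzero change of 1.0 °C
#> 4 interday_dec   1.00  0.998    1.01 per median nonzero change of 1.5 °C
#> 5 intraday_hot   1.07  1.01     1.13 per median nonzero change of 10.2 °C
#> 6 intraday_cold  1.03  1.00     1.06 per median nonzero change of 7.8 °C
```

The generator's truth here has its minimum at 19 °C with cold risk
rising 1% per °C below it, so `cold = 1.25` at −0.5 °C (≈ 19.5 °C below
the MMT) is close to the true `exp(0.01 × 19.5) ≈ 1.22`; the index rows
are the per-median-change relative risks of the four variation terms.
Real data come in through `read_daily_series("city.csv")`, results go
out with `write_results_tables(res, "out/")`, the cumulative curve plots
with `autoplot(res$curve)`, and `run_sensitivity_suite(series)` re-runs
the analysis under six specification variants (trend 6/10 df per year,
equally spaced knots, no variation terms, indices restricted above their
95th percentile, humidity adjustment).

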