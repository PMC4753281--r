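#' Configuration for the synthetic daily-series generator
#'
#' Describes a city-like climate and a known mortality truth with the
#' same structure the analysis model assumes: a seasonal temperature
#' cycle with AR(1) noise, a diurnal-range process coupled to the
#' season, and overdispersed daily counts whose log mean carries a
#' non-linear lagged temperature surface (a V-shaped curve distributed
#' over lags with normalised weights) plus the four linear
#' variation-index effects computed from the true MMT.
#'
#' Defaults emulate a London-like temperate climate (annual mean 11 degC,
#' amplitude 7 degC) with a V-shaped temperature-mortality curve whose
#' minimum sits at 19 degC, near the warm tail as observed in temperate
#' European cities.
#'
#' @param n_years Length of the series in years (default 20).
#' @param seed Integer seed; (seed, config) fully determine the output.
#' @param climate List: `annual_mean` and `annual_amplitude` (degC) of
#'   the seasonal cycle peaking in mid-July, `ar1` autocorrelation of the
#'   daily anomaly, `noise_sd` its stationary (marginal) sd in degC.
#' @param dtr List: `mean` and `seasonal_amplitude` (degC) of the diurnal
#'   range (larger in summer), `noise_sd`, and a positive `floor`.
#' @param mortality List: `baseline` expected deaths/day,
#'   `seasonal_amplitude` on the log scale (winter excess), `dow` seven
#'   log-scale day-of-week effects (Monday first), `heat_slope` and
#'   `cold_slope` of the V-shaped cumulative log-RR per degC away from
#'   `true_mmt`, `lag_decay` geometric decay ratio of the per-lag weights
#'   (`w_l` proportional to `decay^l`, normalised to sum 1 over lags
#'   0..`max_lag`; optionally a length-2 vector giving separate heat and
#'   cold decays), `gamma`, `delta`, `phi`, `vartheta` per-degC linear
#'   effects of the four variation indices, `dispersion` target Pearson
#'   overdispersion factor (>= 1), and optional `nonexternal_fraction`
#'   to emit a second cause stratum by binomial thinning.
#' @param humidity List or NULL: `mean` (%), `seasonal_amplitude`,
#'   `noise_sd`.
#' @param true_mmt Temperature of minimum mortality in the truth (degC).
#' @param max_lag Lag span of the true surface (21).
#' @param start_date First calendar day of the series.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_years = 20, seed = 1L,
                         climate = list(annual_mean = 11, annual_amplitude = 7,
                                        ar1 = 0.7, noise_sd = 3),
                         dtr = list(mean = 8, seasonal_amplitude = 2,
                                    noise_sd = 1.5, floor = 0.5),
                         mortality = list(baseline = 80,
                                          seasonal_amplitude = 0.10,
                                          dow = c(0, -0.005, -0.01, -0.005, 0, 0.02, 0.015),
                                          heat_slope = 0.015, cold_slope = 0.010,
                                          lag_decay = 0.75,
                                          gamma = 0.005, delta = 0.003,
                                          phi = 0.002, vartheta = 0.001,
                                          dispersion = 1.3,
                                          nonexternal_fraction = NULL),
                         humidity = list(mean = 75, seasonal_amplitude = 8,
                                         noise_sd = 8),
                         true_mmt = 19, max_lag = 21L,
                         start_date = as.Date("2000-01-01")) {
  defaults <- formals(synth_config)
  for (nm in c("climate", "dtr", "mortality", "humidity")) {
    if (is.null(get(nm)) && nm != "humidity") abort(sprintf("`%s` must be a list.", nm))
    def <- eval(defaults[[nm]])
    cur <- get(nm)
    if (!is.null(cur)) {
      miss <- setdiff(names(def), names(cur))
      cur[miss] <- def[miss]
      assign(nm, cur)
    }
  }
  stopifnot(climate$ar1 >= 0, climate$ar1 < 1, dtr$floor > 0,
            mortality$dispersion >= 1, length(mortality$dow) == 7)
  structure(list(n_years = n_years, seed = as.integer(seed),
                 climate = climate, dtr = dtr, mortality = mortality,
                 humidity = humidity, true_mmt = true_mmt,
                 max_lag = as.integer(max_lag),
                 start_date = as.Date(start_date)),
            class = "synth_config")
}

# seasonal phase: day-of-year of the temperature peak (mid-July)
.peak_doy <- 199

seasonal_cos <- function(dates, peak_doy = .peak_doy) {
  doy <- as.numeric(format(dates, "%j"))
  cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Generate synthetic daily weather
#'
#' Mean temperature is an annual sinusoid (peaking mid-July) plus AR(1)
#' noise with the configured marginal sd; the diurnal range is a
#' floor-truncated seasonal process (wider in summer); `tmin`/`tmax`
#' bracket `tmean` symmetrically. A 21-day pre-series lag history is
#' attached as an attribute so death generation has complete lag windows
#' from day one. Output is bit-identical for identical (seed, config).
#'
#' @param config A [synth_config()].
#' @return A [daily_series] with `date`, `tmean`, `tmin`, `tmax`,
#'   `humidity`; attribute `lag_history` (pre-series tmean, oldest
#'   first).
#' @export
generate_weather <- function(config) {
  n <- round(config$n_years * 365.25)
  burn <- 200L                       # AR(1) spin-up
  pre <- config$max_lag              # pre-series lag history kept
  ntot <- n + burn + pre
  cl <- config$climate
  with_seed(config$seed, {
    innov_sd <- cl$noise_sd * sqrt(1 - cl$ar1^2)
    e <- numeric(ntot)
    eps <- rnorm(ntot, 0, innov_sd)
    e[1] <- rnorm(1, 0, cl$noise_sd)
    for (t in 2:ntot) e[t] <- cl$ar1 * e[t - 1] + eps[t]
    dates_all <- seq(config$start_date - burn - pre, by = "day", length.out = ntot)
    tmean_all <- cl$annual_mean + cl$annual_amplitude * seasonal_cos(dates_all) + e
    dtr_all <- pmax(config$dtr$floor,
                    config$dtr$mean +
                      config$dtr$seasonal_amplitude * seasonal_cos(dates_all) +
                      rnorm(ntot, 0, config$dtr$noise_sd))
    keep <- (burn + pre + 1):ntot
    hist_idx <- (burn + 1):(burn + pre)
    hum <- if (!is.null(config$humidity)) {
      h <- config$humidity
      pmin(100, pmax(5, h$mean - h$seasonal_amplitude * seasonal_cos(dates_all) +
                       rnorm(ntot, 0, h$noise_sd)))
    } else rep(NA_real_, ntot)
    out <- tibble::tibble(date = dates_all[keep],
                          tmean = tmean_all[keep],
                          tmin = tmean_all[keep] - dtr_all[keep] / 2,
                          tmax = tmean_all[keep] + dtr_all[keep] / 2,
                          humidity = hum[keep])
    out <- daily_series(out, city_label = "synthetic")
    attr(out, "lag_history") <- tmean_all[hist_idx]
    out
  })
}

# V-shaped cumulative log relative risk, zero at the true MMT
true_log_rr <- function(config, x) {
  m <- config$mortality
  ifelse(x >= config$true_mmt,
         m$heat_slope * (x - config$true_mmt),
         m$cold_slope * (config$true_mmt - x))
}

#' True cumulative relative risk of a synthetic configuration
#'
#' Closed-form truth used as the target in recovery tests:
#' `exp(g(x))` where `g` is the configured V-shaped cumulative log-RR
#' with `g(true_mmt) = 0`.
#'
#' @param config A [synth_config()].
#' @param x Temperature(s) in degrees C.
#' @return Relative risk(s).
#' @export
true_cumulative_rr <- function(config, x) {
  exp(true_log_rr(config, x))
}

# per-lag weights: geometric decay, normalised to sum to 1
lag_weights <- function(decay, max_lag) {
  w <- decay^(0:max_lag)
  w / sum(w)
}

#' Generate synthetic daily deaths
#'
#' Draws daily death counts from the log-linear truth
#' `log mu_t = log(baseline) + seasonal + dow + sum_l w_l g(x_{t-l})
#' + gamma inc_t + delta dec_t + phi hot_t + vartheta cold_t`,
#' with the four variation indices computed from the true MMT, per-lag
#' weights summing to 1 so the lag-cumulated curve equals `g` exactly,
#' and counts Poisson or gamma-mixed Poisson (negative binomial with
#' shape chosen so the Pearson dispersion of a correctly specified fit
#' is asymptotically the configured factor).
#'
#' @param weather A series from [generate_weather()] (its `lag_history`
#'   attribute, when present, supplies the pre-series exposure; otherwise
#'   the first value is extended backwards).
#' @param config The same [synth_config()].
#' @return The weather series with a `deaths` column added (and
#'   `deaths_nonexternal` when `nonexternal_fraction` is set); attributes
#'   `true_mu` (expected counts) and `truth` (the config).
#' @export
generate_deaths <- function(weather, config) {
  m <- config$mortality
  L <- config$max_lag
  n <- nrow(weather)
  hist <- attr(weather, "lag_history") %||% rep(weather$tmean[1], L)
  x_ext <- c(hist, weather$tmean)        # length n + L, day t at index t + L
  decay <- m$lag_decay
  if (length(decay) == 1) decay <- c(decay, decay)   # heat, cold
  w_heat <- lag_weights(decay[1], L)
  w_cold <- lag_weights(decay[2], L)
  g_heat <- ifelse(x_ext >= config$true_mmt,
                   m$heat_slope * (x_ext - config$true_mmt), 0)
  g_cold <- ifelse(x_ext < config$true_mmt,
                   m$cold_slope * (config$true_mmt - x_ext), 0)
  lag_term <- numeric(n)
  for (l in 0:L) {
    idx <- (L + 1):(L + n) - l
    lag_term <- lag_term + w_heat[l + 1] * g_heat[idx] + w_cold[l + 1] * g_cold[idx]
  }
  # indices from the TRUE mmt; day-1 interday change uses the last
  # pre-series day so the truth has no boundary artefact
  prev <- c(x_ext[L], weather$tmean[-n])
  inc <- pmax(weather$tmean - pmax(prev, config$true_mmt), 0)
  dec <- pmax(pmin(prev, config$true_mmt) - weather$tmean, 0)
  dtr <- weather$tmax - weather$tmin
  hot <- ifelse(weather$tmean > config$true_mmt, dtr, 0)
  cold <- ifelse(weather$tmean < config$true_mmt, dtr, 0)
  dow_i <- as.integer(format(weather$date, "%u"))
  log_mu <- log(m$baseline) +
    m$seasonal_amplitude * (-seasonal_cos(weather$date)) +   # winter excess
    m$dow[dow_i] +
    lag_term +
    m$gamma * inc + m$delta * dec + m$phi * hot + m$vartheta * cold
  mu <- exp(log_mu)
  with_seed(config$seed + 1L, {
    if (m$dispersion > 1) {
      # gamma-mixed Poisson: Var = mu + mu^2/shape; shape set from the
      # average mu so the Pearson dispersion is ~ the target factor
      shape <- mean(mu) / (m$dispersion - 1)
      deaths <- rpois(n, mu * rgamma(n, shape = shape, rate = shape))
    } else {
      deaths <- rpois(n, mu)
    }
    weather$deaths <- deaths
    if (!is.null(m$nonexternal_fraction)) {
      weather$deaths_nonexternal <- rbinom(n, deaths, m$nonexternal_fraction)
    }
  })
  out <- daily_series(weather, city_label = attr(weather, "city_label"))
  attr(out, "lag_history") <- attr(weather, "lag_history")
  attr(out, "true_mu") <- mu
  attr(out, "truth") <- config
  out
}

#' Generate a complete synthetic city series
#'
#' Convenience wrapper: [generate_weather()] then [generate_deaths()].
#'
#' @param config A [synth_config()].
#' @return A [daily_series] with temperatures, humidity and deaths.
#' @export
generate_city <- function(config = synth_config()) {
  generate_deaths(generate_weather(config), config)
}
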