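#' Interday temperature-variation indices
#'
#' Splits the change in mean temperature between two neighboring days
#' into an increase above and a decrease below the minimum mortality
#' temperature (MMT):
#' \deqn{inc_t = \max[x_t - \max(x_{t-1}, MMT), 0]}
#' \deqn{dec_t = \max[\min(x_{t-1}, MMT) - x_t, 0]}
#' so that, e.g., 25 degC today after 18 degC yesterday with MMT 20 gives
#' inc = 5, dec = 0, and 10 degC after 16 degC gives inc = 0, dec = 6.
#' Day 1 has no predecessor and is set to 0 for both.
#'
#' @param tmean Daily mean temperature vector (degrees C), length >= 2.
#' @param mmt Minimum mortality temperature (degrees C).
#' @return Tibble with columns `interday_inc`, `interday_dec` (both >= 0,
#'   at most one nonzero per day); attribute `mmt_used`.
#' @export
interday_indices <- function(tmean, mmt) {
  if (length(tmean) < 2) abort("`tmean` needs at least 2 days.")
  prev <- dplyr::lag(tmean)
  inc <- pmax(tmean - pmax(prev, mmt), 0)
  dec <- pmax(pmin(prev, mmt) - tmean, 0)
  inc[1] <- 0; dec[1] <- 0
  out <- tibble::tibble(interday_inc = inc, interday_dec = dec)
  attr(out, "mmt_used") <- mmt
  out
}

#' Intraday temperature-variation indices
#'
#' Classifies the diurnal temperature range (DTR, `tmax - tmin`) by
#' whether the day's mean temperature lies above (hot) or below (cold)
#' the MMT; a day with `tmean` exactly at the MMT contributes to neither.
#'
#' @param tmin,tmax,tmean Daily temperature vectors (degrees C).
#' @param mmt Minimum mortality temperature (degrees C).
#' @return Tibble with columns `intraday_hot`, `intraday_cold`;
#'   attribute `mmt_used`.
#' @export
intraday_indices <- function(tmin, tmax, tmean, mmt) {
  if (any(tmin > tmax, na.rm = TRUE)) abort("`tmin` must be <= `tmax`.")
  dtr <- tmax - tmin
  out <- tibble::tibble(
    intraday_hot  = ifelse(tmean > mmt, dtr, 0),
    intraday_cold = ifelse(tmean < mmt, dtr, 0)
  )
  attr(out, "mmt_used") <- mmt
  out
}

#' All four variation indices for a daily series
#'
#' @param series A [daily_series] with `tmean`, `tmin`, `tmax`.
#' @param mmt The MMT (degrees C), typically from [estimate_mmt()].
#' @return Tibble of class `variation_indices` with the four index
#'   columns; attribute `mmt_used`.
#' @export
variation_indices <- function(series, mmt) {
  inter <- interday_indices(series$tmean, mmt)
  intra <- intraday_indices(series$tmin, series$tmax, series$tmean, mmt)
  out <- dplyr::bind_cols(inter, intra)
  structure(out, class = c("variation_indices", class(out)), mmt_used = mmt)
}

#' Restrict an index to extreme days
#'
#' Keeps only values above the `pct`-th percentile of the nonzero values;
#' everything at or below the threshold is set to 0. Used to probe
#' associations with extreme inter- and intraday changes.
#'
#' @param index Non-negative numeric vector.
#' @param pct Percentile in (0, 100), default 95.
#' @return Vector of the same length.
#' @export
restrict_to_extremes <- function(index, pct = 95) {
  nz <- index[!is.na(index) & index > 0]
  if (!length(nz)) {
    warn("Index has no nonzero values; returned unchanged.")
    return(index)
  }
  thr <- quantile(nz, pct / 100, names = FALSE)
  ifelse(!is.na(index) & index > thr, index, ifelse(is.na(index), NA_real_, 0))
}

#' Summary table for variation indices
#'
#' Per index: count and percentage of nonzero days, and
#' min/25th/median/75th/max computed over nonzero days only (days with a
#' zero value are excluded, matching how diurnal-range summaries are
#' conventionally reported).
#'
#' @param indices A [variation_indices] tibble (or any tibble of
#'   non-negative index columns).
#' @return Tibble, one row per index.
#' @export
summarize_indices <- function(indices) {
  purrr::map_dfr(names(indices), function(nm) {
    v <- indices[[nm]]
    n_days <- sum(!is.na(v))
    nz <- v[!is.na(v) & v > 0]
    q <- if (length(nz)) quantile(nz, c(0, .25, .5, .75, 1), names = FALSE)
         else rep(NA_real_, 5)
    tibble::tibble(index = nm, n_nonzero = length(nz),
                   pct_nonzero = 100 * length(nz) / n_days,
                   min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5])
  })
}

#' Estimate the minimum mortality temperature
#'
#' Step 1 of the two-step procedure: fits the simple model with only the
#' cross-basis of mean temperature (plus the seasonal trend spline and
#' day-of-week indicators), computes the overall cumulative curve over a
#' search grid spanning the empirical 1st-99th percentiles of `tmean` at
#' 0.1 degC resolution, and takes the MMT as the temperature minimising
#' the cumulated log relative risk. Ties are broken toward the grid value
#' nearest the series median temperature. When the curve is flat (range
#' of the cumulated log-RR below `flat_tol`) the MMT is still reported
#' but flagged.
#'
#' @param series A [daily_series] with `deaths`.
#' @param config An [analysis_config()].
#' @return Object of class `mmt_result`: list with `mmt`,
#'   `mmt_percentile` (empirical percentile of `tmean` at the MMT),
#'   `search_grid`, `curve` (re-referenced at the MMT), `flat`, `fit`,
#'   and `crossbasis`.
#' @export
estimate_mmt <- function(series, config = analysis_config()) {
  cb <- series_crossbasis(series, config)
  des <- build_design(series, cb, indices = NULL, config = config)
  fit <- fit_quasipoisson(des$y, des$X, roles = des$roles)
  tm <- series$tmean[!is.na(series$tmean)]
  grid <- percentile_grid(tm, config$mmt_grid_percentiles, config$mmt_grid_step)
  med <- median(tm)
  # reference choice does not affect the argmin; use the grid point
  # nearest the median as a stable provisional reference
  ref0 <- grid[which.min(abs(grid - med))]
  curve0 <- cumulative_curve(fit, cb, grid, ref_temp = ref0)
  lo <- min(curve0$log_rr)
  cand <- grid[curve0$log_rr <= lo + 1e-12]
  mmt <- cand[which.min(abs(cand - med))]
  flat <- diff(range(curve0$log_rr)) < config$flat_tol
  if (flat) warn("Cumulative curve is flat over the search grid; MMT is weakly identified.")
  curve <- cumulative_curve(fit, cb, grid, ref_temp = mmt)
  structure(list(mmt = mmt,
                 mmt_percentile = 100 * mean(tm <= mmt),
                 search_grid = grid, curve = curve, flat = flat,
                 fit = fit, crossbasis = cb),
            class = "mmt_result")
}

#' @export
print.mmt_result <- function(x, ...) {
  cat(sprintf("MMT %.1f °C (%s percentile of mean temperature)%s\n",
              x$mmt, ordinal(x$mmt_percentile), if (x$flat) " [curve flat]" else ""))
  invisible(x)
}
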