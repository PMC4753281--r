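#' Heat and cold relative risks
#'
#' Summarises the cumulative exposure-response curve as the relative risk
#' at the empirical 99th (heat) and 1st (cold) percentiles of mean daily
#' temperature, with the MMT as the reference, and Wald 95% intervals on
#' the log scale.
#'
#' @param curve A [cumulative_curve] referenced at the MMT.
#' @param tmean Mean daily temperature vector used to compute the
#'   percentiles.
#' @param percentiles Percentiles (fractions) for heat and cold.
#' @return Tibble with two rows (`heat`, `cold`) and columns `label`,
#'   `rr`, `ci_low`, `ci_high`, `contrast`.
#' @export
heat_cold_rr <- function(curve, tmean, percentiles = c(heat = 0.99, cold = 0.01)) {
  tm <- tmean[!is.na(tmean)]
  qs <- quantile(tm, percentiles, names = FALSE)
  grid_rng <- range(curve$temp)
  if (any(qs < grid_rng[1] - 1e-9 | qs > grid_rng[2] + 1e-9)) {
    warn("Report percentile outside the curve grid; evaluating beyond it.")
  }
  pt <- eval_curve(curve, qs)
  tibble::tibble(
    label = c("heat", "cold"),
    rr = pt$rr, ci_low = pt$rr_low, ci_high = pt$rr_high,
    contrast = sprintf("%s pct (%.1f °C) vs MMT (%.1f °C)",
                       ordinal(100 * percentiles), qs, attr(curve, "ref_temp"))
  )
}

#' Relative risk per median change of a variation index
#'
#' The linear coefficient of a variation index is scaled to the median of
#' the index's nonzero values (zero days excluded by default, matching
#' how the index distributions are summarised), and reported as
#' `RR = exp(coef * m)` with `CI = exp((coef +/- 1.959964 se) * m)`.
#'
#' @param fit A [fit_quasipoisson] result containing the index term.
#' @param index_name One of `interday_inc`, `interday_dec`,
#'   `intraday_hot`, `intraday_cold`.
#' @param indices The [variation_indices] tibble the model was fitted
#'   with.
#' @param zero_days Include zero days in the median? Default `FALSE`.
#' @return One-row tibble (`label`, `rr`, `ci_low`, `ci_high`,
#'   `contrast`), or a row of NAs with an explanatory contrast when the
#'   index is all zero.
#' @export
rr_per_median <- function(fit, index_name, indices, zero_days = FALSE) {
  if (!index_name %in% names(fit$coef)) {
    abort(sprintf("Fit has no coefficient `%s`.", index_name))
  }
  v <- indices[[index_name]]
  v <- v[!is.na(v)]
  vals <- if (zero_days) v else v[v > 0]
  if (!length(vals)) {
    return(tibble::tibble(label = index_name, rr = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          contrast = "undefined: index has no nonzero days"))
  }
  m <- median(vals)
  b <- unname(fit$coef[index_name])
  se <- unname(fit$se[index_name])
  z <- 1.959964
  tibble::tibble(label = index_name,
                 rr = exp(b * m),
                 ci_low = exp((b - z * se) * m),
                 ci_high = exp((b + z * se) * m),
                 contrast = sprintf("per median nonzero change of %.1f °C", m))
}

#' Pearson correlations among the temperature measures
#'
#' Correlation matrix over mean daily temperature and the four variation
#' indices, computed over all study days (zero index days included).
#' Constant columns give undefined entries, flagged with a warning.
#'
#' @param tmean Mean daily temperature vector.
#' @param indices A [variation_indices] tibble aligned with `tmean`.
#' @return 5x5 symmetric matrix with unit diagonal.
#' @export
temperature_correlations <- function(tmean, indices) {
  m <- cbind(tmean = tmean,
             as.matrix(tibble::as_tibble(indices)[, c("interday_inc", "interday_dec",
                                                      "intraday_hot", "intraday_cold")]))
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warn(sprintf("Constant column(s): %s; correlations undefined there.",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  out <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(out) <- 1
  out
}
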