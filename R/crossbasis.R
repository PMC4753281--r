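#' Build the exposure-lag cross-basis
#'
#' Constructs the tensor-product design expressing a bidimensional
#' exposure-lag-response surface: entry `(t, (j,k))` equals
#' `sum_{l=0..max_lag} b_j(x[t-l]) * c_k(l)`, where `b` is the exposure
#' basis (here a quadratic B-spline over temperature) and `c` the
#' lag basis (a natural cubic spline over lag 0..max_lag). Rows whose
#' lag window reaches before the start of the series, or contains a
#' missing exposure, are flagged invalid and carry NA.
#'
#' The cross-basis is not centered at construction; all referencing to
#' the minimum mortality temperature happens later through basis
#' differences in [cumulative_curve()], so the design matrix does not
#' depend on the (later-estimated) MMT.
#'
#' @param tmean Daily mean temperature vector (degrees C), NA allowed.
#' @param var_spec [spline_spec] for the exposure dimension.
#' @param lag_spec [spline_spec] for the lag dimension (domain
#'   `0..max_lag`).
#' @param max_lag Maximum lag in days (default 21).
#' @return An object of class `crossbasis`: list with `matrix`
#'   (days x (var dim * lag dim)), `var_spec`, `lag_spec`, `max_lag`,
#'   `column_index` (tibble mapping column to (j, k)), and `valid_rows`.
#' @export
build_crossbasis <- function(tmean, var_spec, lag_spec, max_lag = 21L) {
  max_lag <- as.integer(max_lag)
  n <- length(tmean)
  if (n <= max_lag) abort("Series must be longer than `max_lag`.")
  B <- spline_basis(tmean, var_spec)                 # n x J
  C <- spline_basis(seq(0L, max_lag), lag_spec)      # (max_lag+1) x K
  J <- ncol(B); K <- ncol(C)
  cb <- matrix(0, n, J * K)
  # column (j-1)*K + k holds sum_l B[t-l, j] * C[l+1, k]
  jj <- rep(seq_len(J), each = K)
  kk <- rep(seq_len(K), times = J)
  for (l in 0:max_lag) {
    Bl <- rbind(matrix(NA_real_, l, J), B[seq_len(n - l), , drop = FALSE])
    cb <- cb + Bl[, jj, drop = FALSE] *
      matrix(C[l + 1, kk], n, J * K, byrow = TRUE)
  }
  colnames(cb) <- paste0("cb", jj, ".", kk)
  valid <- !apply(is.na(cb), 1, any)
  structure(list(matrix = cb,
                 var_spec = var_spec, lag_spec = lag_spec,
                 max_lag = max_lag,
                 column_index = tibble::tibble(column = colnames(cb), j = jj, k = kk),
                 valid_rows = valid),
            class = "crossbasis")
}

#' @export
print.crossbasis <- function(x, ...) {
  cat(sprintf("<crossbasis> %d days x %d terms (exposure dim %d x lag dim %d), lags 0-%d, %d valid rows\n",
              nrow(x$matrix), ncol(x$matrix),
              max(x$column_index$j), max(x$column_index$k),
              x$max_lag, sum(x$valid_rows)))
  invisible(x)
}

# percentile grid spanning [q_lo, q_hi] at `step` resolution, endpoints kept
percentile_grid <- function(tm, probs, step) {
  qs <- quantile(tm, probs, names = FALSE)
  unique(c(seq(qs[1], qs[2], by = step), qs[2]))
}

ordinal <- function(n) {
  n <- round(n)
  suff <- ifelse(n %% 100 %in% 11:13, "th",
                 c("th", "st", "nd", "rd", rep("th", 6))[n %% 10 + 1])
  paste0(n, suff)
}

# contrast matrix for overall cumulative predictions at `x` vs `ref`:
# row for grid point x has entries (b_j(x) - b_j(ref)) * S_k with
# S_k = sum_l c_k(l)
cumulative_contrast <- function(cb, x, ref) {
  Bx <- spline_basis(x, cb$var_spec)
  Br <- spline_basis(ref, cb$var_spec)
  S <- colSums(spline_basis(seq(0L, cb$max_lag), cb$lag_spec))
  D <- sweep(Bx, 2, as.numeric(Br))          # b_j(x) - b_j(ref)
  out <- D[, cb$column_index$j, drop = FALSE] *
    matrix(S[cb$column_index$k], nrow(D), nrow(cb$column_index), byrow = TRUE)
  colnames(out) <- cb$column_index$column
  out
}

#' Overall cumulative exposure-response curve
#'
#' Sums the fitted exposure-lag surface over the whole lag period to give
#' the net (lag-cumulated) log relative risk at each temperature of a
#' grid, relative to a reference temperature, with delta-method standard
#' errors from the fit's scaled covariance. At the reference temperature
#' the log-RR and its standard error are exactly zero.
#'
#' @param fit A [fit_quasipoisson] result containing coefficients for
#'   every cross-basis column.
#' @param cb The [build_crossbasis] object used in the fit.
#' @param grid Temperature grid (degrees C).
#' @param ref_temp Reference temperature (typically the MMT).
#' @param conf_level Confidence level for the Wald interval on RR.
#' @return A tibble of class `cumulative_curve` with columns `temp`,
#'   `log_rr`, `se_log_rr`, `rr`, `rr_low`, `rr_high`; attributes
#'   `ref_temp` and `eval` (a function evaluating the curve at arbitrary
#'   temperatures).
#' @export
cumulative_curve <- function(fit, cb, grid, ref_temp, conf_level = 0.95) {
  cols <- cb$column_index$column
  if (!all(cols %in% names(fit$coef))) {
    abort("Fit is missing coefficients for some cross-basis columns.")
  }
  rng <- range(cb$var_spec$boundary_knots)
  if (ref_temp < rng[1] - 1e-8 || ref_temp > rng[2] + 1e-8) {
    warn(sprintf("Reference temperature %.2f outside the fitted range [%.2f, %.2f].",
                 ref_temp, rng[1], rng[2]))
  }
  beta <- fit$coef[cols]
  V <- fit$vcov[cols, cols, drop = FALSE]
  z <- qnorm(1 - (1 - conf_level) / 2)
  eval_at <- function(x) {
    Cm <- cumulative_contrast(cb, x, ref_temp)
    log_rr <- drop(Cm %*% beta)
    se <- sqrt(pmax(rowSums((Cm %*% V) * Cm), 0))
    # exact zero at the reference: the contrast row is identically zero
    at_ref <- abs(x - ref_temp) < 1e-12
    log_rr[at_ref] <- 0; se[at_ref] <- 0
    tibble::tibble(temp = x, log_rr = log_rr, se_log_rr = se,
                   rr = exp(log_rr),
                   rr_low = exp(log_rr - z * se),
                   rr_high = exp(log_rr + z * se))
  }
  out <- eval_at(as.numeric(grid))
  structure(out, class = c("cumulative_curve", class(out)),
            ref_temp = ref_temp, conf_level = conf_level, eval = eval_at)
}

#' Evaluate a cumulative curve at new temperatures
#'
#' @param curve A [cumulative_curve] object.
#' @param temp Temperatures at which to evaluate.
#' @return Tibble with the same columns as the curve.
#' @export
eval_curve <- function(curve, temp) {
  attr(curve, "eval")(as.numeric(temp))
}

#' Export a cumulative curve as plain columns
#'
#' @param curve A [cumulative_curve].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve)[, c("temp", "rr", "rr_low", "rr_high")], path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cumulative_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temp, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rr_low, ymax = .data$rr_high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "ref_temp"),
                        linetype = 3, colour = "grey40") +
    ggplot2::labs(x = "Mean daily temperature (°C)",
                  y = "Relative risk (cumulative, lags 0-21)") +
    ggplot2::theme_minimal()
}
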