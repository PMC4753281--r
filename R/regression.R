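#' Analysis configuration
#'
#' Collects the tunable choices of the modelling strategy. The defaults
#' reproduce the main analysis: quadratic B-spline over temperature with
#' 3 internal knots at the 10th/75th/90th percentiles, natural cubic
#' lag spline with 3 knots equally spaced on the log-lag scale plus an
#' intercept over 21 days of lag, a natural cubic trend spline with 8
#' degrees of freedom per study year, and day-of-week indicators.
#'
#' @param knot_percentiles Exposure-basis internal knot percentiles
#'   (fractions), default `c(.10, .75, .90)`.
#' @param knot_mode `"percentile"` (default) or `"equal"` (3 internal
#'   knots equally spaced in the range of the variable, a sensitivity
#'   variant).
#' @param max_lag Maximum lag in days (21).
#' @param lag_knots Number of interior lag knots (3).
#' @param trend_df_per_year Degrees of freedom per study year for the
#'   seasonal trend spline (8; sensitivity 6 or 10).
#' @param include_variation_terms Add the four variation indices to the
#'   step-2 model?
#' @param include_humidity Add a 3-df natural spline of mean relative
#'   humidity?
#' @param extreme_restriction Restrict index definitions to days above
#'   the `extreme_pct` percentile of their nonzero values?
#' @param extreme_pct Percentile for the extreme restriction (95).
#' @param report_percentiles Temperature percentiles for the heat and
#'   cold summaries, `c(heat = .99, cold = .01)`.
#' @param mmt_grid_percentiles Trim for the MMT search grid
#'   (`c(.01, .99)`).
#' @param mmt_grid_step MMT grid resolution in degrees C (0.1).
#' @param flat_tol Log-RR range below which the step-1 curve is flagged
#'   flat.
#' @param median_zero_days Include zero days in the median used to scale
#'   the per-median relative risks? Default `FALSE` (nonzero-day median).
#' @param response Name of the count column to model (default
#'   `"deaths"`).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(knot_percentiles = c(0.10, 0.75, 0.90),
                            knot_mode = c("percentile", "equal"),
                            max_lag = 21L,
                            lag_knots = 3L,
                            trend_df_per_year = 8,
                            include_variation_terms = TRUE,
                            include_humidity = FALSE,
                            extreme_restriction = FALSE,
                            extreme_pct = 95,
                            report_percentiles = c(heat = 0.99, cold = 0.01),
                            mmt_grid_percentiles = c(0.01, 0.99),
                            mmt_grid_step = 0.1,
                            flat_tol = 1e-6,
                            median_zero_days = FALSE,
                            response = "deaths") {
  knot_mode <- match.arg(knot_mode)
  structure(list(knot_percentiles = knot_percentiles, knot_mode = knot_mode,
                 max_lag = as.integer(max_lag), lag_knots = as.integer(lag_knots),
                 trend_df_per_year = trend_df_per_year,
                 include_variation_terms = include_variation_terms,
                 include_humidity = include_humidity,
                 extreme_restriction = extreme_restriction,
                 extreme_pct = extreme_pct,
                 report_percentiles = report_percentiles,
                 mmt_grid_percentiles = mmt_grid_percentiles,
                 mmt_grid_step = mmt_grid_step,
                 flat_tol = flat_tol,
                 median_zero_days = median_zero_days,
                 response = response),
            class = "analysis_config")
}

# exposure and lag spline specs for a series under a config, and the
# cross-basis built from them; both steps of the pipeline reuse this so
# the two models share identical basis objects
series_crossbasis <- function(series, config) {
  tm <- series$tmean[!is.na(series$tmean)]
  bk <- range(tm)
  ik <- if (config$knot_mode == "percentile") {
    quantile(tm, config$knot_percentiles, names = FALSE)
  } else {
    seq(bk[1], bk[2], length.out = 5)[2:4]
  }
  var_spec <- spline_spec("quadratic-bspline", internal_knots = ik,
                          boundary_knots = bk, intercept = FALSE)
  lag_spec <- spline_spec("natural-cubic",
                          internal_knots = log_lag_knots(config$max_lag, config$lag_knots),
                          boundary_knots = c(0, config$max_lag), intercept = TRUE)
  build_crossbasis(series$tmean, var_spec, lag_spec, config$max_lag)
}

#' Assemble the regression design matrix
#'
#' Builds the design of the quasi-Poisson mortality model: intercept,
#' cross-basis columns, optionally the four variation-index columns
#' (entering linearly at lag 0, untransformed degrees C), a natural cubic
#' spline of the sequential day index with `8 x study years` degrees of
#' freedom (rounded), six day-of-week indicators (Monday reference), and
#' optionally a 3-df natural spline of mean relative humidity. Rows with
#' an incomplete 0-21-day lag window, or a missing response or covariate,
#' are masked out of the fit.
#'
#' @param series A [daily_series].
#' @param cb A [build_crossbasis] object aligned with `series`.
#' @param indices A [variation_indices] tibble, or `NULL` for the step-1
#'   (MMT) model.
#' @param config An [analysis_config()].
#' @return List with `X` (design matrix), `y` (counts), `mask` (logical
#'   rows used), and `roles` (tibble term -> role).
#' @export
build_design <- function(series, cb, indices = NULL, config = analysis_config()) {
  n <- nrow(series)
  y <- series[[config$response]]
  if (is.null(y)) abort(sprintf("Series has no `%s` column.", config$response))

  parts <- list(`(Intercept)` = matrix(1, n, 1,
                                       dimnames = list(NULL, "(Intercept)")))
  roles <- tibble::tibble(term = "(Intercept)", role = "intercept")

  parts$cb <- cb$matrix
  roles <- dplyr::bind_rows(roles, tibble::tibble(term = colnames(cb$matrix),
                                                  role = "crossbasis"))

  if (!is.null(indices)) {
    im <- as.matrix(tibble::as_tibble(indices)[, c("interday_inc", "interday_dec",
                                                   "intraday_hot", "intraday_cold")])
    parts$idx <- im
    roles <- dplyr::bind_rows(roles, tibble::tibble(term = colnames(im), role = "index"))
  }

  day_index <- seq_len(n)
  years <- n / 365.25
  trend_df <- max(2L, as.integer(round(config$trend_df_per_year * years)))
  # equally spaced knots over the day index (internal knots at interior
  # quantiles of a uniform grid are equally spaced)
  tr <- splines::ns(day_index, df = trend_df)
  colnames(tr) <- paste0("trend", seq_len(ncol(tr)))
  parts$trend <- tr
  roles <- dplyr::bind_rows(roles, tibble::tibble(term = colnames(tr), role = "trend"))

  dow <- factor(format(series$date, "%u"), levels = as.character(1:7),
                labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  dm <- stats::model.matrix(~dow)[, -1, drop = FALSE]
  parts$dow <- dm
  roles <- dplyr::bind_rows(roles, tibble::tibble(term = colnames(dm), role = "dow"))

  if (isTRUE(config$include_humidity)) {
    if (is.null(series$humidity)) abort("`include_humidity = TRUE` but series has no humidity column.")
    hm <- matrix(NA_real_, n, 3)
    ok <- !is.na(series$humidity)
    hm[ok, ] <- splines::ns(series$humidity[ok], df = 3)
    colnames(hm) <- paste0("hum", 1:3)
    parts$hum <- hm
    roles <- dplyr::bind_rows(roles, tibble::tibble(term = colnames(hm), role = "humidity"))
  }

  X <- do.call(cbind, parts)
  colnames(X) <- roles$term
  mask <- cb$valid_rows & !is.na(y) & stats::complete.cases(X)
  Xm <- X[mask, , drop = FALSE]
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
    abort(paste0("Design is rank deficient after masking; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  list(X = X, y = y, mask = mask, roles = roles)
}

#' Fit an overdispersed Poisson model
#'
#' Maximum-likelihood Poisson regression with log link via iteratively
#' reweighted least squares; overdispersion is handled quasi-likelihood
#' style, scaling the covariance by the Pearson dispersion
#' `sum((y - mu)^2 / mu) / (n - p)`. Point estimates are therefore the
#' Poisson ML solution and standard errors are
#' `sqrt(dispersion)` times the Poisson ones. Convergence is declared
#' when the relative deviance change falls below 1e-9, within 100
#' iterations.
#'
#' @param y Non-negative counts.
#' @param X Design matrix including an intercept column, full column
#'   rank. A `mask` of rows may be supplied; defaults to complete rows.
#' @param roles Optional tibble (term, role) of column bookkeeping.
#' @param mask Logical vector of rows to use.
#' @return Object of class `qp_fit`: `coef`, `vcov` (scaled), `se`,
#'   `dispersion`, `n_obs`, `deviance`, `fitted`, `converged`,
#'   `iterations`, `roles`, `mask`.
#' @export
fit_quasipoisson <- function(y, X, roles = NULL, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(y) & stats::complete.cases(X)
  yy <- y[mask]
  XX <- X[mask, , drop = FALSE]
  n <- length(yy); p <- ncol(XX)
  if (any(yy < 0)) abort("Counts must be non-negative.")
  if (n <= p) abort("Fewer usable rows than parameters.")
  if (all(yy == yy[1])) abort("Response has zero variance.")

  mu <- yy + 0.1
  eta <- log(mu)
  dev_old <- Inf
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(100)) {
    w <- mu
    z <- eta + (yy - mu) / mu
    XtWX <- crossprod(XX * sqrt(w))
    ch <- tryCatch(chol(XtWX), error = function(e) {
      abort("IRLS normal equations are singular; check the design for collinearity.")
    })
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XX, w * z)))
    eta <- drop(XX %*% beta)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(yy > 0, yy * log(yy / mu), 0) - (yy - mu))
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < 1e-9) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    abort(sprintf("IRLS did not converge in 100 iterations (last deviance %.6g).", dev_old))
  }
  dispersion <- sum((yy - mu)^2 / mu) / (n - p)
  # Fisher information evaluated at the converged estimate
  XtWX <- crossprod(XX * sqrt(mu))
  Finv <- chol2inv(chol(XtWX))
  vcov <- dispersion * Finv
  cf <- drop(beta)
  names(cf) <- colnames(XX)
  dimnames(vcov) <- list(colnames(XX), colnames(XX))
  structure(list(coef = cf, vcov = vcov, se = sqrt(diag(vcov)),
                 dispersion = dispersion, n_obs = n, deviance = dev_old,
                 fitted = mu, eta = eta, converged = converged,
                 iterations = it, roles = roles, mask = mask),
            class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("<qp_fit> quasi-Poisson, %d obs, %d terms, dispersion %.3f, deviance %.1f (%d IRLS iterations)\n",
              x$n_obs, length(x$coef), x$dispersion, x$deviance, x$iterations))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qp_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                        std.error = unname(x$se),
                        statistic = unname(x$coef / x$se),
                        p.value = 2 * stats::pnorm(-abs(unname(x$coef / x$se))))
  if (!is.null(x$roles)) out <- dplyr::left_join(out, x$roles, by = "term")
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' @exportS3Method generics::glance
glance.qp_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_terms = length(x$coef),
                 dispersion = x$dispersion, deviance = x$deviance,
                 iterations = x$iterations, converged = x$converged)
}
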