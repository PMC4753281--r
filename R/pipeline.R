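#' Run the two-step city analysis
#'
#' Step 1 fits the simple model with only the cross-basis of mean daily
#' temperature (plus trend and day-of-week) and estimates the MMT as the
#' minimum of the overall cumulative curve. Step 2 computes the four
#' variation indices from that MMT, adds them to the model (linearly, at
#' lag 0), refits, and summarises: heat/cold relative risks at the 99th
#' and 1st temperature percentiles versus the MMT, the four
#' per-median-change relative risks, the index summary table, the
#' correlation table, and the cumulative exposure-response curve. Both
#' steps reuse identical basis objects, so the step-1 design is a column
#' subset of the step-2 design.
#'
#' @param series A [daily_series] with `deaths`.
#' @param config An [analysis_config()].
#' @return Object of class `city_analysis`: list with `mmt`
#'   ([estimate_mmt] result), `indices`, `fit` (step-2 [fit_quasipoisson]),
#'   `curve` (step-2 cumulative curve referenced at the MMT),
#'   `rr_summary` (6 rows: heat, cold, four indices), `index_summary`,
#'   `correlations`, `config`, and `manifest` (knots, MMT, n_obs,
#'   dispersion).
#' @export
run_city_analysis <- function(series, config = analysis_config()) {
  series <- daily_series(series, city_label = attr(series, "city_label"))
  step1 <- estimate_mmt(series, config)
  cb <- step1$crossbasis

  indices <- NULL
  if (config$include_variation_terms) {
    indices <- variation_indices(series, step1$mmt)
    if (isTRUE(config$extreme_restriction)) {
      for (nm in names(indices)) {
        indices[[nm]] <- restrict_to_extremes(indices[[nm]], config$extreme_pct)
      }
    }
  }

  des <- build_design(series, cb, indices = indices, config = config)
  fit <- fit_quasipoisson(des$y, des$X, roles = des$roles)

  tm <- series$tmean[!is.na(series$tmean)]
  grid <- percentile_grid(tm, config$mmt_grid_percentiles, config$mmt_grid_step)
  curve <- cumulative_curve(fit, cb, grid, ref_temp = step1$mmt)

  rr <- heat_cold_rr(curve, series$tmean, config$report_percentiles)
  if (!is.null(indices)) {
    rr <- dplyr::bind_rows(
      rr,
      purrr::map_dfr(c("interday_inc", "interday_dec",
                       "intraday_hot", "intraday_cold"),
                     ~rr_per_median(fit, .x, indices,
                                    zero_days = config$median_zero_days))
    )
  }

  structure(list(
    city_label = attr(series, "city_label"),
    mmt = step1,
    indices = indices,
    fit = fit,
    curve = curve,
    rr_summary = rr,
    index_summary = if (!is.null(indices)) summarize_indices(indices) else NULL,
    correlations = if (!is.null(indices)) temperature_correlations(series$tmean, indices) else NULL,
    config = config,
    manifest = tibble::tibble(
      city = attr(series, "city_label") %||% NA_character_,
      n_days = nrow(series), n_obs = fit$n_obs,
      mmt = step1$mmt, mmt_percentile = step1$mmt_percentile,
      dispersion = fit$dispersion,
      var_knots = paste(signif(cb$var_spec$internal_knots, 4), collapse = "/"),
      lag_knots = paste(signif(cb$lag_spec$internal_knots, 4), collapse = "/"),
      trend_terms = sum(fit$roles$role == "trend"))
  ), class = "city_analysis")
}

#' @export
print.city_analysis <- function(x, ...) {
  cat(sprintf("<city_analysis>%s %d obs, MMT %.1f °C (%s pct), dispersion %.2f\n",
              if (is.null(x$city_label)) "" else paste0(" [", x$city_label, "]"),
              x$fit$n_obs, x$mmt$mmt, ordinal(x$mmt$mmt_percentile), x$fit$dispersion))
  print(x$rr_summary)
  invisible(x)
}

sensitivity_variants <- function() {
  c("trend_6df", "trend_10df", "knots_equal", "no_variation",
    "extremes_95", "humidity")
}

#' Run the sensitivity-analysis suite
#'
#' Re-runs the analysis under the six variants probing the robustness of
#' the main specification: 6 or 10 trend df per year instead of 8,
#' equally spaced instead of percentile-placed exposure knots, a model
#' without the variation terms, indices restricted to days above the
#' 95th percentile of their nonzero values, and adjustment for mean
#' relative humidity (3-df natural spline). The humidity variant is
#' skipped with a warning when the series has no humidity column.
#'
#' @param series A [daily_series] with `deaths`.
#' @param config The main [analysis_config()].
#' @param flag_threshold Absolute RR difference from the main analysis
#'   above which a variant is flagged.
#' @return Tibble of class `sensitivity_suite`: one row per variant per
#'   effect measure, columns `variant`, `label`, `rr`, `ci_low`,
#'   `ci_high`, `rr_main`, `delta_rr`, `flagged`.
#' @export
run_sensitivity_suite <- function(series, config = analysis_config(),
                                  flag_threshold = 0.05) {
  variants <- list(main = config)
  cfg <- function(...) {
    out <- config
    mods <- list(...)
    out[names(mods)] <- mods
    out
  }
  variants$trend_6df <- cfg(trend_df_per_year = 6)
  variants$trend_10df <- cfg(trend_df_per_year = 10)
  variants$knots_equal <- cfg(knot_mode = "equal")
  variants$no_variation <- cfg(include_variation_terms = FALSE)
  variants$extremes_95 <- cfg(extreme_restriction = TRUE)
  if (!is.null(series$humidity) && any(!is.na(series$humidity))) {
    variants$humidity <- cfg(include_humidity = TRUE)
  } else {
    warn("Series has no humidity data; humidity variant skipped.")
  }
  rows <- purrr::imap_dfr(variants, function(vcfg, nm) {
    res <- run_city_analysis(series, vcfg)
    dplyr::mutate(res$rr_summary, variant = nm, .before = 1)
  })
  main <- rows[rows$variant == "main", c("label", "rr")]
  names(main)[2] <- "rr_main"
  out <- dplyr::left_join(rows, main, by = "label")
  out <- dplyr::mutate(out,
                       delta_rr = .data$rr - .data$rr_main,
                       flagged = abs(.data$delta_rr) > flag_threshold)
  structure(out, class = c("sensitivity_suite", class(out)))
}

#' Write the analysis result tables
#'
#' Emits the three report tables of a completed run as CSV: the index
#' summary (nonzero-day counts and quantiles), the Pearson correlation
#' table among the five temperature measures, and the relative-risk
#' table (heat, cold and the four indices with 95% CIs), plus the
#' cumulative curve export.
#'
#' @param results A [run_city_analysis] result (with variation terms).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the file paths, invisibly.
#' @export
write_results_tables <- function(results, out_dir) {
  if (!inherits(results, "city_analysis")) abort("`results` must be a city_analysis.")
  if (is.null(results$rr_summary) || !nrow(results$rr_summary)) {
    abort("Results are empty; nothing to write.")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(index_summary = file.path(out_dir, "index_summary.csv"),
             correlations = file.path(out_dir, "temperature_correlations.csv"),
             rr = file.path(out_dir, "rr_estimates.csv"),
             curve = file.path(out_dir, "cumulative_curve.csv"))
  if (is.null(results$index_summary) || is.null(results$correlations)) {
    abort("Results lack the index tables; run with `include_variation_terms = TRUE`.")
  }
  readr::write_csv(results$index_summary, paths["index_summary"])
  cor_df <- tibble::as_tibble(results$correlations, rownames = "measure")
  readr::write_csv(cor_df, paths["correlations"])
  readr::write_csv(results$rr_summary, paths["rr"])
  write_curve(results$curve, paths["curve"])
  invisible(paths)
}

#' Plot the relative-risk summary
#'
#' Forest-style display of the heat/cold and variation-index relative
#' risks of one analysis.
#'
#' @param results A [run_city_analysis] result.
#' @return A ggplot object.
#' @export
plot_rr_summary <- function(results) {
  df <- dplyr::mutate(results$rr_summary,
                      label = factor(.data$label, levels = rev(.data$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Relative risk (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
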