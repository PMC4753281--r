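null_curve <- function(series, cfg = analysis_config()) {
  m <- estimate_mmt(series, cfg)
  fit0 <- m$fit
  fit0$coef[] <- 0
  cumulative_curve(fit0, m$crossbasis, m$search_grid, ref_temp = m$mmt)
}

test_that("a null fit yields unit heat and cold relative risks", {
  series <- generate_city(small_config(seed = 6, n_years = 3))
  curve <- null_curve(series)
  rr <- heat_cold_rr(curve, series$tmean)
  expect_equal(rr$rr, c(1, 1))
  expect_equal(rr$label, c("heat", "cold"))
})

test_that("heat and cold contrasts sit at the reporting percentiles of tmean", {
  series <- generate_city(small_config(seed = 6, n_years = 3))
  res <- run_city_analysis(series)
  qs <- quantile(series$tmean, c(0.99, 0.01), names = FALSE)
  hc <- res$rr_summary[res$rr_summary$label %in% c("heat", "cold"), ]
  pt <- eval_curve(res$curve, qs)
  expect_equal(hc$rr, pt$rr, tolerance = 1e-12)
})

test_that("per-median relative risk follows the direct arithmetic", {
  idx <- tibble::tibble(interday_inc = c(0, 5, 5, 5, 0))
  fit <- structure(list(coef = c(interday_inc = 0.01),
                        se = c(interday_inc = 0.002)), class = "qp_fit")
  out <- rr_per_median(fit, "interday_inc", idx)
  expect_equal(out$rr, exp(0.05))
  expect_equal(out$ci_low, exp((0.01 - 1.959964 * 0.002) * 5))
  expect_equal(out$ci_high, exp((0.01 + 1.959964 * 0.002) * 5))

  fit0 <- structure(list(coef = c(interday_inc = 0),
                         se = c(interday_inc = 0.002)), class = "qp_fit")
  expect_equal(rr_per_median(fit0, "interday_inc", idx)$rr, 1)

  all0 <- tibble::tibble(interday_inc = rep(0, 5))
  und <- rr_per_median(fit, "interday_inc", all0)
  expect_true(is.na(und$rr))
  expect_match(und$contrast, "undefined")
})

test_that("rescaling an index leaves the per-median relative risk invariant", {
  set.seed(19)
  n <- 1500
  idx_val <- ifelse(runif(n) < 0.3, rexp(n, 0.5), 0)
  X <- cbind(`(Intercept)` = 1, z = rnorm(n), interday_inc = idx_val)
  y <- rpois(n, exp(3 + 0.1 * X[, "z"] + 0.02 * idx_val))
  fit1 <- fit_quasipoisson(y, X)
  X2 <- X; X2[, "interday_inc"] <- 2 * idx_val
  fit2 <- fit_quasipoisson(y, X2)
  i1 <- tibble::tibble(interday_inc = idx_val)
  i2 <- tibble::tibble(interday_inc = 2 * idx_val)
  r1 <- rr_per_median(fit1, "interday_inc", i1)
  r2 <- rr_per_median(fit2, "interday_inc", i2)
  expect_equal(fit2$coef["interday_inc"], fit1$coef["interday_inc"] / 2,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(r1$rr, r2$rr, tolerance = 1e-8)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-8)
})

test_that("correlation table is symmetric with unit diagonal and matches the textbook formula", {
  series <- generate_city(small_config(seed = 10, n_years = 3))
  idx <- variation_indices(series, 19)
  cm <- temperature_correlations(series$tmean, idx)
  expect_equal(dim(cm), c(5, 5))
  expect_equal(diag(cm), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))
  # textbook Pearson for one off-diagonal pair
  a <- series$tmean; b <- idx$interday_inc
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cm["tmean", "interday_inc"], r, tolerance = 1e-12)
  # structurally disjoint supports: inc x dec elementwise product is zero
  expect_lte(cm["interday_inc", "interday_dec"], 0.05)
})

test_that("heat/cold relative risks are invariant to the day-of-week reference", {
  series <- generate_city(small_config(seed = 15, n_years = 3))
  cfg <- analysis_config()
  cb <- thermovar:::series_crossbasis(series, cfg)
  des <- build_design(series, cb, config = cfg)
  fit1 <- fit_quasipoisson(des$y, des$X, roles = des$roles)
  # recode: swap reference day by replacing the Tuesday indicator with Monday
  dow_terms <- des$roles$term[des$roles$role == "dow"]
  X2 <- des$X
  is_mon <- X2[, dow_terms] %*% rep(1, length(dow_terms)) == 0
  X2[, dow_terms[1]] <- as.numeric(is_mon)   # now indicator of Monday, ref Tuesday
  fit2 <- fit_quasipoisson(des$y, X2, roles = des$roles)
  grid <- quantile(series$tmean, c(.01, .5, .99), names = FALSE)
  c1 <- cumulative_curve(fit1, cb, grid, ref_temp = grid[2])
  c2 <- cumulative_curve(fit2, cb, grid, ref_temp = grid[2])
  expect_equal(c1$log_rr, c2$log_rr, tolerance = 1e-6)
  expect_equal(c1$se_log_rr, c2$se_log_rr, tolerance = 1e-6)
})
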