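make_cb <- function(x, max_lag = 21) {
  build_crossbasis(x, random_var_spec(x), default_lag_spec(max_lag), max_lag)
}

test_that("constant exposure gives identical valid cross-basis rows", {
  x <- rep(12, 60)
  spec <- spline_spec("quadratic-bspline", internal_knots = c(10, 14, 16),
                      boundary_knots = c(0, 20), intercept = FALSE)
  cb <- build_crossbasis(x, spec, default_lag_spec(), 21)
  valid <- cb$matrix[cb$valid_rows, ]
  expect_false(any(cb$valid_rows[1:21]))
  expect_lt(max(abs(sweep(valid, 2, valid[1, ]))), 1e-12)
})

test_that("cross-basis entries match the naive triple-loop oracle", {
  set.seed(33)
  x <- cumsum(rnorm(200, 0, 1.5)) + 10
  cb <- make_cb(x)
  naive <- naive_crossbasis(x, cb$var_spec, cb$lag_spec, cb$max_lag)
  expect_lt(max(abs(cb$matrix[cb$valid_rows, ] - naive[cb$valid_rows, ])), 1e-10)
})

test_that("max_lag = 0 degenerates to the same-day exposure basis", {
  set.seed(5)
  x <- runif(50, 0, 20)
  spec0 <- spline_spec("quadratic-bspline", internal_knots = c(5, 10, 15),
                       boundary_knots = c(0, 20), intercept = FALSE)
  # lag basis at the single lag 0 is the 1-column constant (intercept)
  lag0 <- spline_spec("natural-cubic", internal_knots = 0.5,
                      boundary_knots = c(0, 1), intercept = TRUE)
  cb <- build_crossbasis(x, spec0, lag0, 0)
  C0 <- spline_basis(0, lag0)
  B <- bspline_basis(x, spec0)
  # each (j,k) column is b_j(x_t) * c_k(0)
  for (r in seq_len(nrow(cb$column_index))) {
    j <- cb$column_index$j[r]; k <- cb$column_index$k[r]
    expect_equal(cb$matrix[, r], B[, j] * C0[1, k], tolerance = 1e-12)
  }
})

test_that("missing exposures invalidate exactly the overlapping lag windows", {
  set.seed(9)
  x <- runif(120, 0, 20)
  x[50] <- NA
  spec <- spline_spec("quadratic-bspline", internal_knots = c(5, 10, 15),
                      boundary_knots = c(0, 20), intercept = FALSE)
  cb <- build_crossbasis(x, spec, default_lag_spec(), 21)
  expect_false(any(cb$valid_rows[50:71]))
  expect_true(all(cb$valid_rows[c(22:49, 72:120)]))
})

test_that("series shorter than the lag span is rejected", {
  spec <- spline_spec("quadratic-bspline", internal_knots = 5,
                      boundary_knots = c(0, 10), intercept = FALSE)
  expect_error(build_crossbasis(runif(21, 0, 10), spec, default_lag_spec(), 21),
               "longer than")
})

fit_toy <- function(seed = 11, n = 300) {
  set.seed(seed)
  x <- 10 + cumsum(rnorm(n, 0, 1.2))
  cb <- make_cb(x)
  eta <- log(30) + 0.02 * scale(x)[, 1]
  y <- rpois(n, exp(eta))
  X <- cbind(`(Intercept)` = 1, cb$matrix)
  fit <- fit_quasipoisson(y, X, mask = cb$valid_rows)
  list(x = x, cb = cb, fit = fit)
}

test_that("cumulative curve is zero (with zero se) at its reference", {
  toy <- fit_toy()
  ref <- median(toy$x)
  grid <- c(quantile(toy$x, c(.05, .5, .95), names = FALSE), ref)
  curve <- cumulative_curve(toy$fit, toy$cb, grid, ref_temp = ref)
  at_ref <- which(curve$temp == ref)
  expect_equal(curve$log_rr[at_ref], c(0, 0))
  expect_equal(curve$se_log_rr[at_ref], c(0, 0))
  expect_true(all(curve$se_log_rr >= 0))
  expect_true(all(curve$rr_low <= curve$rr & curve$rr <= curve$rr_high))
})

test_that("null coefficients give a flat unit curve", {
  toy <- fit_toy()
  fit0 <- toy$fit
  fit0$coef[] <- 0
  curve <- cumulative_curve(fit0, toy$cb, seq(5, 15, 1), ref_temp = 10)
  expect_equal(curve$log_rr, rep(0, nrow(curve)))
  expect_equal(curve$rr, rep(1, nrow(curve)))
})

test_that("cumulative log-RR matches the per-lag summation oracle", {
  toy <- fit_toy(seed = 21)
  ref <- quantile(toy$x, 0.6, names = FALSE)
  grid <- quantile(toy$x, seq(.02, .98, length.out = 15), names = FALSE)
  curve <- cumulative_curve(toy$fit, toy$cb, grid, ref_temp = ref)
  oracle <- naive_cumulative_logrr(toy$fit$coef, toy$cb, grid, ref)
  expect_lt(max(abs(curve$log_rr - oracle)), 1e-10)
})

test_that("refining the grid never changes values at shared points", {
  toy <- fit_toy(seed = 4)
  ref <- median(toy$x)
  g1 <- seq(quantile(toy$x, .05), quantile(toy$x, .95), length.out = 21)
  g2 <- seq(min(g1), max(g1), length.out = 41)   # contains g1's points
  c1 <- cumulative_curve(toy$fit, toy$cb, g1, ref_temp = ref)
  c2 <- cumulative_curve(toy$fit, toy$cb, g2, ref_temp = ref)
  shared <- match(round(g1, 10), round(g2, 10))
  expect_true(all(!is.na(shared)))
  expect_equal(c1$log_rr, c2$log_rr[shared], tolerance = 1e-12)
})

test_that("the curve depends on coefficients only through contrasts", {
  # shifting the coefficient of every (j, k) column by c_j * a_k changes
  # the linear predictor like an exposure-only term; the cumulated curve
  # must shift only through the contrast b_j(x) - b_j(ref), so adding a
  # constant to the *fitted intercept* or to terms constant in x leaves
  # it untouched
  toy <- fit_toy(seed = 8)
  ref <- median(toy$x)
  grid <- quantile(toy$x, c(.1, .5, .9), names = FALSE)
  c1 <- cumulative_curve(toy$fit, toy$cb, grid, ref_temp = ref)
  fit2 <- toy$fit
  fit2$coef["(Intercept)"] <- fit2$coef["(Intercept)"] + 5
  c2 <- cumulative_curve(fit2, toy$cb, grid, ref_temp = ref)
  expect_equal(c1$log_rr, c2$log_rr)
  expect_equal(c1$se_log_rr, c2$se_log_rr)
})
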