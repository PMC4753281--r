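test_that("quadratic B-spline full basis is a partition of unity, also at knots", {
  spec <- spline_spec("quadratic-bspline", internal_knots = c(4, 11, 16),
                      boundary_knots = c(-3, 25), intercept = TRUE)
  x <- c(seq(-3, 25, length.out = 101), 4, 11, 16, 4 - 1e-9, 4 + 1e-9)
  B <- bspline_basis(x, spec)
  expect_equal(ncol(B), 6)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  # continuity across an internal knot
  at <- bspline_basis(c(4 - 1e-8, 4, 4 + 1e-8), spec)
  expect_lt(max(abs(at[1, ] - at[3, ])), 1e-6)
  expect_lt(max(abs(at[2, ] - at[1, ])), 1e-6)
})

test_that("quadratic B-spline matches an independent Cox-de Boor recursion", {
  set.seed(71)
  for (rep in 1:5) {
    bk <- sort(runif(2, -10, 30))
    ik <- sort(runif(3, bk[1] + 0.5, bk[2] - 0.5))
    spec <- spline_spec("quadratic-bspline", internal_knots = ik,
                        boundary_knots = bk, intercept = TRUE)
    x <- runif(40, bk[1], bk[2])
    expect_lt(max(abs(bspline_basis(x, spec) - coxdeboor_basis(x, ik, bk))), 1e-10)
  }
})

test_that("out-of-boundary B-spline values extend the end polynomials", {
  spec <- spline_spec("quadratic-bspline", internal_knots = c(5, 10, 15),
                      boundary_knots = c(0, 20), intercept = TRUE)
  expect_warning(Bout <- bspline_basis(c(-2, 22), spec), "boundary")
  # each column beyond the boundary must continue the quadratic of the
  # end segment: fit that quadratic from three inside points near the edge
  xs <- c(0, 0.1, 0.2)
  Bin <- bspline_basis(xs, spec)
  for (j in seq_len(ncol(Bin))) {
    co <- solve(cbind(1, xs, xs^2), Bin[, j])
    expect_equal(unname(Bout[1, j]), sum(co * c(1, -2, 4)), tolerance = 1e-7)
  }
})

test_that("natural cubic basis is linear beyond the boundary knots", {
  spec <- spline_spec("natural-cubic", internal_knots = c(3, 9, 14),
                      boundary_knots = c(0, 21), intercept = TRUE)
  xo <- seq(22, 30, by = 0.5)
  B <- natural_cubic_basis(xo, spec)
  second_diff <- diff(B, differences = 2)
  expect_lt(max(abs(second_diff)), 1e-6 * max(abs(B)))
  xl <- seq(-9, -1, by = 0.5)
  expect_lt(max(abs(diff(natural_cubic_basis(xl, spec), differences = 2))), 1e-6)
})

test_that("natural cubic basis reproduces affine functions exactly", {
  spec <- spline_spec("natural-cubic", internal_knots = c(2, 5, 12),
                      boundary_knots = c(0, 21), intercept = TRUE)
  x <- seq(0, 21, by = 0.25)
  B <- natural_cubic_basis(x, spec)
  y <- 3.5 - 0.7 * x
  fitted <- B %*% qr.solve(B, y)
  expect_lt(max(abs(fitted - y)), 1e-8)
})

test_that("natural cubic regression agrees with a truncated-power construction", {
  set.seed(22)
  x <- sort(runif(60, 0, 10))
  y <- sin(x) + rnorm(60, 0, 0.2)
  knots <- c(0, 2.5, 5, 7.5, 10)   # boundary + internal
  spec <- spline_spec("natural-cubic", internal_knots = knots[2:4],
                      boundary_knots = knots[c(1, 5)], intercept = TRUE)
  B <- natural_cubic_basis(x, spec)
  Tp <- truncated_power_natural(x, knots)
  f1 <- B %*% qr.solve(B, y)
  f2 <- Tp %*% qr.solve(Tp, y)
  expect_lt(max(abs(f1 - f2)), 1e-8)
})

test_that("log-scale lag knots are geometrically equally spaced", {
  k <- log_lag_knots(21, 3)
  expect_length(k, 3)
  expect_true(all(diff(k) > 0) && all(k > 0) && all(k < 21))
  ratios <- diff(log(c(1, k, 21)))
  expect_lt(max(abs(ratios - ratios[1])), 1e-12)
  expect_equal(log_lag_knots(21, 1), exp((log(1) + log(21)) / 2))
  expect_error(log_lag_knots(0, 3), "max_lag")
})

test_that("basis construction is deterministic and validates its spec", {
  spec <- spline_spec("quadratic-bspline", internal_knots = c(1, 2),
                      boundary_knots = c(0, 5), intercept = FALSE)
  x <- runif(20, 0, 5)
  expect_identical(bspline_basis(x, spec), bspline_basis(x, spec))
  expect_error(spline_spec("quadratic-bspline", internal_knots = c(2, 1),
                           boundary_knots = c(0, 5)), "increasing")
  expect_error(spline_spec("natural-cubic", internal_knots = c(6),
                           boundary_knots = c(0, 5)), "inside")
})
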