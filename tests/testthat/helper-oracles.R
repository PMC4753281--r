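# Independent reference implementations used as test oracles.
# These deliberately share no code with the package internals.

# Cox-de Boor recursion for one B-spline basis function N_{i,deg}(x)
# over a full (replicated-boundary) knot vector; 0/0 := 0, and the
# right boundary point is assigned to the last non-empty span.
coxdeboor <- function(x, knots, i, deg) {
  if (deg == 0) {
    hi <- knots[i + 1]
    at_end <- hi == knots[length(knots)] && x == hi
    return(as.numeric((x >= knots[i] && x < hi) || at_end))
  }
  d1 <- knots[i + deg] - knots[i]
  d2 <- knots[i + deg + 1] - knots[i + 1]
  a <- if (d1 > 0) (x - knots[i]) / d1 * coxdeboor(x, knots, i, deg - 1) else 0
  b <- if (d2 > 0) (knots[i + deg + 1] - x) / d2 * coxdeboor(x, knots, i + 1, deg - 1) else 0
  a + b
}

coxdeboor_basis <- function(x, internal, boundary, deg = 2) {
  kn <- sort(c(rep(boundary, each = deg + 1), internal))
  ncols <- length(internal) + deg + 1
  sapply(seq_len(ncols), function(i) sapply(x, coxdeboor, knots = kn, i = i, deg = deg))
}

# Truncated-power-basis natural cubic spline design (with intercept):
# {1, x, d_k(x) - d_{K-1}(x)} with d_k(x) = [(x-xi_k)_+^3 - (x-xi_K)_+^3] / (xi_K - xi_k)
truncated_power_natural <- function(x, knots) {
  knots <- sort(knots)
  K <- length(knots)
  d <- function(k) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  cols <- lapply(seq_len(K - 2), function(k) d(k) - d(K - 1))
  cbind(1, x, do.call(cbind, cols))
}

# Naive triple-loop cross-basis: entry (t, (j,k)) = sum_l b_j(x[t-l]) c_k(l)
naive_crossbasis <- function(x, var_spec, lag_spec, max_lag) {
  B <- spline_basis(x, var_spec)
  C <- spline_basis(0:max_lag, lag_spec)
  n <- length(x); J <- ncol(B); K <- ncol(C)
  out <- matrix(NA_real_, n, J * K)
  for (t in (max_lag + 1):n) {
    col <- 0
    for (j in seq_len(J)) {
      for (k in seq_len(K)) {
        col <- col + 1
        s <- 0
        for (l in 0:max_lag) s <- s + B[t - l, j] * C[l + 1, k]
        out[t, col] <- s
      }
    }
  }
  out
}

# Per-lag summation path for the overall cumulative log relative risk:
# sum_l sum_j (b_j(x) - b_j(ref)) * sum_k beta_jk c_k(l)
naive_cumulative_logrr <- function(beta, cb, x, ref) {
  B <- function(v) spline_basis(v, cb$var_spec)
  C <- spline_basis(0:cb$max_lag, cb$lag_spec)
  J <- max(cb$column_index$j); K <- max(cb$column_index$k)
  bm <- matrix(beta[cb$column_index$column], J, K, byrow = TRUE)
  sapply(x, function(xi) {
    db <- drop(B(xi)) - drop(B(ref))
    total <- 0
    for (l in 0:cb$max_lag) {
      for (j in seq_len(J)) {
        total <- total + db[j] * sum(bm[j, ] * C[l + 1, ])
      }
    }
    total
  })
}

# Independent Poisson ML fitter: damped Newton on the log-likelihood,
# coded without reference to the package's IRLS.
newton_poisson <- function(y, X, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - exp(eta))
  }
  ll <- loglik(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X * sqrt(mu))
    step <- solve(H, grad)
    fac <- 1
    repeat {
      cand <- beta + fac * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) break
    }
    beta <- beta + fac * step
    ll_new <- loglik(beta)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) break
    ll <- ll_new
  }
  beta
}

# Case-analysis oracle for the interday indices, derived independently:
# an increase counts only above the MMT, a decrease only below it.
oracle_interday <- function(today, prev, mmt) {
  inc <- if (today > mmt && today > prev) today - max(prev, mmt) else 0
  dec <- if (today < mmt && today < prev) min(prev, mmt) - today else 0
  c(inc = inc, dec = dec)
}

# Small synthetic fixtures shared across test files
small_config <- function(seed = 1L, n_years = 4, ...) {
  synth_config(n_years = n_years, seed = seed, ...)
}

# A strong, low-noise signal so single-seed recovery checks are sharp
strong_config <- function(seed = 1L, n_years = 8) {
  synth_config(n_years = n_years, seed = seed,
               mortality = list(baseline = 120, heat_slope = 0.06,
                                cold_slope = 0.04, dispersion = 1))
}

random_var_spec <- function(x) {
  spline_spec("quadratic-bspline",
              internal_knots = quantile(x, c(.10, .75, .90), names = FALSE),
              boundary_knots = range(x), intercept = FALSE)
}

default_lag_spec <- function(max_lag = 21) {
  spline_spec("natural-cubic", internal_knots = log_lag_knots(max_lag, 3),
              boundary_knots = c(0, max_lag), intercept = TRUE)
}
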