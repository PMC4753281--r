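#' Spline specification
#'
#' Describes a one-dimensional spline basis: the family, its internal
#' knots, the boundary knots and whether the basis keeps the intercept
#' (constant-spanning) column. The basis dimension is fully determined by
#' these fields.
#'
#' @param family `"quadratic-bspline"` or `"natural-cubic"`.
#' @param internal_knots Strictly increasing numeric vector, strictly
#'   inside the boundary interval. May be empty for the B-spline family.
#' @param boundary_knots Length-2 numeric vector, increasing.
#' @param intercept Keep the full (intercept-complete) basis? For the
#'   quadratic B-spline the full basis satisfies partition of unity; with
#'   `intercept = FALSE` the first column is dropped, the usual choice
#'   when the regression model has its own intercept.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(family = c("quadratic-bspline", "natural-cubic"),
                        internal_knots = numeric(),
                        boundary_knots,
                        intercept = FALSE) {
  family <- match.arg(family)
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2 || diff(boundary_knots) <= 0) {
    abort("`boundary_knots` must be two increasing values.")
  }
  if (length(internal_knots)) {
    if (is.unsorted(internal_knots, strictly = TRUE)) {
      abort("`internal_knots` must be strictly increasing.")
    }
    if (min(internal_knots) <= boundary_knots[1] ||
        max(internal_knots) >= boundary_knots[2]) {
      abort("`internal_knots` must lie strictly inside the boundary interval.")
    }
  }
  if (family == "natural-cubic" && length(internal_knots) < 1) {
    abort("natural-cubic spec needs at least one internal knot.")
  }
  structure(list(family = family, internal_knots = internal_knots,
                 boundary_knots = boundary_knots, intercept = isTRUE(intercept)),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("<spline_spec> %s | knots: %s | boundary: [%g, %g] | intercept: %s\n",
              x$family, paste(signif(x$internal_knots, 4), collapse = ", "),
              x$boundary_knots[1], x$boundary_knots[2], x$intercept))
  invisible(x)
}

basis_dim <- function(spec) {
  k <- length(spec$internal_knots)
  n <- switch(spec$family,
              "quadratic-bspline" = k + 3L,   # internal + degree + 1
              "natural-cubic"     = k + 2L)   # natural space incl. constant
  if (!spec$intercept) n <- n - 1L
  as.integer(n)
}

#' Evaluate a spline basis
#'
#' `spline_basis()` dispatches on the spec's family; `bspline_basis()` and
#' `natural_cubic_basis()` are the two families. Values of `x` outside the
#' boundary interval are handled by polynomial extension of the end
#' segments (quadratic Taylor extension for the B-spline, the natural
#' linear extension for the natural cubic spline) and raise a warning,
#' since a prediction grid may exceed the fitting range.
#'
#' @param x Numeric vector of evaluation points (NA allowed, propagated).
#' @param spec A [spline_spec].
#' @return Numeric matrix, `length(x)` rows, [basis_dim] columns.
#' @export
spline_basis <- function(x, spec) {
  switch(spec$family,
         "quadratic-bspline" = bspline_basis(x, spec),
         "natural-cubic" = natural_cubic_basis(x, spec))
}

#' @rdname spline_basis
#' @export
bspline_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (spec$family != "quadratic-bspline") abort("spec family must be quadratic-bspline.")
  ord <- 3L  # degree 2
  kn <- sort(c(rep(spec$boundary_knots, each = ord), spec$internal_knots))
  ncols <- length(spec$internal_knots) + ord
  out <- matrix(NA_real_, length(x), ncols)
  ok <- !is.na(x)
  lo <- spec$boundary_knots[1]; hi <- spec$boundary_knots[2]
  inside <- ok & x >= lo & x <= hi
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(kn, x[inside], ord = ord)
  }
  if (any(ok & !inside)) {
    warn("Values outside the boundary knots: using quadratic extension of the end segments.")
    for (side in c(1, 2)) {
      b <- spec$boundary_knots[side]
      sel <- if (side == 1) ok & x < lo else ok & x > hi
      if (!any(sel)) next
      # end segment is a single quadratic polynomial: the Taylor expansion
      # at the boundary (value, 1st, 2nd derivative) extends it exactly
      dmat <- splines::splineDesign(kn, rep(b, 3), ord = ord, derivs = 0:2)
      h <- x[sel] - b
      out[sel, ] <- cbind(1, h, h^2 / 2) %*% dmat
    }
  }
  if (!spec$intercept) out <- out[, -1, drop = FALSE]
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  out
}

#' @rdname spline_basis
#' @export
natural_cubic_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (spec$family != "natural-cubic") abort("spec family must be natural-cubic.")
  out <- matrix(NA_real_, length(x), basis_dim(spec))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok, ] <- splines::ns(x[ok], knots = spec$internal_knots,
                             Boundary.knots = spec$boundary_knots,
                             intercept = spec$intercept)
  }
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  out
}

#' Lag knots equally spaced on the log scale
#'
#' Places `n_knots` interior knots for the lag-response spline at the
#' exponential of equally spaced points spanning `[log 1, log max_lag]`.
#' The log grid is anchored at lag 1 because log 0 is undefined; including
#' the endpoints 1 and `max_lag`, successive knot ratios are all equal.
#'
#' @param max_lag Maximum lag in days (>= 1).
#' @param n_knots Number of interior knots (>= 1).
#' @return Strictly increasing numeric vector of length `n_knots` in
#'   `(0, max_lag)`.
#' @export
log_lag_knots <- function(max_lag, n_knots = 3) {
  if (max_lag < 1) abort("`max_lag` must be >= 1.")
  if (n_knots < 1) abort("`n_knots` must be >= 1.")
  exp(seq(log(1), log(max_lag), length.out = n_knots + 2))[-c(1, n_knots + 2)]
}
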