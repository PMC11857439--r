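#' Cubic B-spline basis specification for the age trajectory
#'
#' Five evenly spaced interior knots over the training age range with
#' clamped (4-fold repeated) boundary knots, cubic order: nine spline
#' columns that form a partition of unity, to which the design matrix
#' appends a constant intercept column.
#'
#' @param age_range Length-2 numeric, the training age range.
#' @param n_interior Number of evenly spaced interior knots (default 5).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `bspline_basis`.
#' @export
bspline_basis <- function(age_range, n_interior = 5L, degree = 3L) {
  age_range <- range(age_range)
  if (diff(age_range) <= 0) abort("`age_range` must span a positive interval")
  interior <- seq(age_range[1], age_range[2],
                  length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  knots <- c(rep(age_range[1], degree + 1L), interior,
             rep(age_range[2], degree + 1L))
  structure(
    list(degree = as.integer(degree), n_interior = as.integer(n_interior),
         knots = knots, age_range = age_range,
         n_spline = n_interior + degree + 1L),
    class = "bspline_basis"
  )
}

#' Basis expansion of ages
#'
#' Evaluates the clamped cubic B-spline basis at each age and appends a
#' constant intercept as the last column. Ages outside the training range
#' are clamped to it (with a warning): extrapolation holds the boundary
#' basis values.
#'
#' @param ages Numeric vector.
#' @param basis A `bspline_basis`.
#' @return Numeric matrix, `length(ages)` by `basis$n_spline + 1`.
#' @export
design_matrix <- function(ages, basis) {
  stopifnot(inherits(basis, "bspline_basis"))
  rng <- basis$age_range
  if (any(ages < rng[1] | ages > rng[2])) {
    warn("ages outside the training range were clamped to it")
    ages <- pmin(pmax(ages, rng[1]), rng[2])
  }
  B <- splines::splineDesign(basis$knots, ages, ord = basis$degree + 1L)
  cbind(B, intercept = 1)
}
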