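#' Fitted log-hazard-ratio curves
#'
#' A risk curve represents the fitted log hazard ratio as a function of an
#' index z score: a B-spline basis with coefficients, a centering offset
#' making the weighted cohort-mean log HR zero, a validity range, and a
#' redundant evaluation grid (z from -4 to 4, step 0.05) with pointwise
#' standard errors for portability.  Outside the validity range the curve is
#' clamped at its boundary values.
#'
#' @name risk_curve
NULL

#' @keywords internal
new_risk_curve <- function(basis, coefficients, centering_offset, Z = NULL,
                           V = NULL, bbar = NULL,
                           z_grid = seq(-4, 4, by = 0.05),
                           log_hr = NULL, pointwise_se = NULL) {
  curve <- structure(list(knots = basis$knots, degree = basis$degree,
                          coefficients = coefficients,
                          centering_offset = centering_offset,
                          valid_range = basis$valid_range,
                          z_grid = z_grid),
                     class = "risk_curve")
  curve$log_hr <- as.numeric(log_hr %||% evaluate_risk_curve(curve, z_grid))
  if (is.null(pointwise_se) && !is.null(V)) {
    # SE of the centered curve a(z)'gamma with a(z) = (B(z) - bbar) Z
    Bg <- eval_basis(list(knots = basis$knots, degree = basis$degree,
                          valid_range = basis$valid_range),
                     pmin(pmax(z_grid, basis$valid_range[1]),
                          basis$valid_range[2]))
    Ac <- sweep(Bg, 2, bbar) %*% Z
    pointwise_se <- sqrt(pmax(0, rowSums((Ac %*% V) * Ac)))
  }
  curve$pointwise_se <- pointwise_se %||% rep(NA_real_, length(z_grid))
  curve
}

#' Evaluate a risk curve
#'
#' Exact B-spline basis evaluation of the centered log hazard ratio; z values
#' outside the curve's validity range are clamped to its boundary (logged via
#' the \code{"n_clamped"} attribute).
#'
#' @param curve A \code{"risk_curve"}.
#' @param z Numeric vector of z scores.
#' @return Log hazard ratios, with attribute \code{"n_clamped"}.
#' @export
evaluate_risk_curve <- function(curve, z) {
  stopifnot(inherits(curve, "risk_curve"), all(is.finite(z)))
  zc <- pmin(pmax(z, curve$valid_range[1]), curve$valid_range[2])
  B <- splines::splineDesign(curve$knots, zc, ord = curve$degree + 1)
  out <- drop(B %*% curve$coefficients) - curve$centering_offset
  attr(out, "n_clamped") <- sum(z != zc)
  out
}

#' Export a risk curve's evaluation grid
#'
#' Data frame in the form used to plot hazard-ratio figures: columns
#' \code{z}, \code{log_hr}, \code{se}, \code{hr}, \code{hr_lo95},
#' \code{hr_hi95}.
#'
#' @param curve A \code{"risk_curve"}.
#' @return Data frame, one row per grid point.
#' @export
risk_curve_grid <- function(curve) {
  stopifnot(inherits(curve, "risk_curve"))
  data.frame(z = curve$z_grid, log_hr = curve$log_hr,
             se = curve$pointwise_se,
             hr = exp(curve$log_hr),
             hr_lo95 = exp(curve$log_hr - 1.959964 * curve$pointwise_se),
             hr_hi95 = exp(curve$log_hr + 1.959964 * curve$pointwise_se))
}

#' @keywords internal
risk_curve_to_list <- function(curve) {
  list(knots = curve$knots, degree = curve$degree,
       coefficients = curve$coefficients,
       centering_offset = curve$centering_offset,
       valid_range = curve$valid_range,
       z_grid = curve$z_grid, log_hr = as.numeric(curve$log_hr),
       pointwise_se = curve$pointwise_se)
}

#' @keywords internal
risk_curve_from_list <- function(x) {
  structure(list(knots = as.numeric(x$knots), degree = as.integer(x$degree),
                 coefficients = as.numeric(x$coefficients),
                 centering_offset = as.numeric(x$centering_offset),
                 valid_range = as.numeric(x$valid_range),
                 z_grid = as.numeric(x$z_grid),
                 log_hr = as.numeric(x$log_hr),
                 pointwise_se = as.numeric(x$pointwise_se)),
            class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, ...) {
  cat("Risk curve: log hazard ratio vs index z score\n")
  cat(sprintf("  B-spline degree %d, %d coefficients; valid z range %.2f to %.2f\n",
              x$degree, length(x$coefficients), x$valid_range[1],
              x$valid_range[2]))
  i <- which.min(x$log_hr[x$z_grid >= x$valid_range[1] &
                          x$z_grid <= x$valid_range[2]])
  zi <- x$z_grid[x$z_grid >= x$valid_range[1] & x$z_grid <= x$valid_range[2]]
  cat(sprintf("  minimum log HR %.3f at z = %.2f (grid)\n",
              min(x$log_hr), zi[i]))
  invisible(x)
}
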