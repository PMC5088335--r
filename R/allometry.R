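#' Allometric circumference models
#'
#' An allometric model expresses a body circumference as a power law in height
#' and weight with a multiplicative sex offset,
#' \deqn{\log C = c_0 + a \log H + b \log W + c f,}
#' fitted by (optionally weighted) least squares on natural logarithms, with C
#' in cm, H in metres and W in kg (the unit convention under which the
#' published hip intercept 2.658 reproduces realistic hip circumferences).
#' The
#' corresponding normalized index rescales an observed circumference to a
#' reference body size,
#' \deqn{C \cdot (H/H_{ref})^{-a} (W/W_{ref})^{-b},}
#' so that the index is uncorrelated with log height and log weight in the
#' fitting sample (it is an affine function of the regression residual).
#'
#' @param intercept Intercept on the log-cm circumference scale (height in
#'   metres, weight in kg).
#' @param height_exponent,weight_exponent Power-law exponents of height (cm)
#'   and weight (kg).
#' @param female_offset Additive log-scale offset for females.
#' @param ref_height_cm,ref_weight_kg Reference body size (cm, kg) at which the
#'   normalized index equals the raw circumference.
#' @param r_squared Coefficient of determination of the log-log fit.
#' @param n_fit Number of records used in the fit.
#' @param residual_sd Weighted residual standard deviation on the log scale.
#' @param se Optional named numeric vector of coefficient standard errors.
#'
#' @return An object of class \code{"allometric_model"}.
#' @seealso [fit_allometric_model()], [apply_allometric_index()], [compute_hi()]
#' @export
allometric_model <- function(intercept, height_exponent, weight_exponent,
                             female_offset, ref_height_cm, ref_weight_kg,
                             r_squared = NA_real_, n_fit = NA_integer_,
                             residual_sd = NA_real_, se = NULL) {
  stopifnot(is.numeric(intercept), is.numeric(height_exponent),
            is.numeric(weight_exponent), is.numeric(female_offset),
            ref_height_cm > 0, ref_weight_kg > 0)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(list(intercept = intercept,
                 height_exponent = height_exponent,
                 weight_exponent = weight_exponent,
                 female_offset = female_offset,
                 ref_height_cm = ref_height_cm,
                 ref_weight_kg = ref_weight_kg,
                 r_squared = r_squared,
                 n_fit = n_fit,
                 residual_sd = residual_sd,
                 se = se),
            class = "allometric_model")
}

#' Published hip allometry model
#'
#' The hip-circumference power law fitted to NHANES III nonpregnant adults,
#' \eqn{\log HC = 2.658 - 0.310 \log H + 0.482 \log W + 0.083 f}
#' (R^2 = 0.887), with reference body size 166 cm / 73 kg.  This is the default
#' model behind [compute_hi()].
#'
#' @return An \code{"allometric_model"}.
#' @export
hip_model_nhanes <- function() {
  allometric_model(intercept = 2.658, height_exponent = -0.310,
                   weight_exponent = 0.482, female_offset = 0.083,
                   ref_height_cm = 166, ref_weight_kg = 73,
                   r_squared = 0.887)
}

#' Fit an allometric circumference model
#'
#' Weighted least squares of the natural log of a circumference on log height,
#' log weight and a female indicator.  Records failing the eligibility gate
#' (pregnant, under 18, nonpositive or missing measurements; see
#' [filter_eligible()]) are excluded before fitting.
#'
#' @param records Cohort data frame in the standard schema (see
#'   [load_cohort()]).
#' @param circumference_field Column to model, \code{"hip_cm"} or
#'   \code{"waist_cm"}.
#' @param use_sample_weights Use the \code{sample_weight} column as regression
#'   weights (default \code{TRUE}).
#' @param round_reference Round the (weighted) mean height/weight to the
#'   nearest integer cm/kg when setting the reference body size (default
#'   \code{TRUE}).
#'
#' @return An \code{"allometric_model"} with coefficient standard errors,
#'   weighted R^2 and residual SD.
#' @export
fit_allometric_model <- function(records, circumference_field = "hip_cm",
                                 use_sample_weights = TRUE,
                                 round_reference = TRUE) {
  if (!circumference_field %in% names(records))
    stop("unknown circumference field: ", circumference_field)
  records <- filter_eligible(records)
  n <- nrow(records)
  if (n < 5L)
    stop("insufficient data: need at least 5 eligible records, have ", n)
  w <- if (use_sample_weights) records$sample_weight else rep(1, n)
  if (sum(w) <= 0) stop("insufficient data: total weight is zero")

  lc <- log(records[[circumference_field]])
  lh <- log(records$height_cm / 100)   # metres: the published unit convention
  lw <- log(records$weight_kg)
  f  <- records$female
  if (stats::var(lh) == 0 || stats::var(lw) == 0)
    stop("singular fit: constant log height or log weight")

  fit <- stats::lm(lc ~ lh + lw + f, weights = w)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("singular fit: collinear design")
  res <- stats::residuals(fit)
  wss_res <- sum(w * res^2)
  mu <- sum(w * lc) / sum(w)
  wss_tot <- sum(w * (lc - mu)^2)
  mh <- sum(w * records$height_cm) / sum(w)
  mw <- sum(w * records$weight_kg) / sum(w)
  if (round_reference) { mh <- round(mh); mw <- round(mw) }

  # a perfect fit makes summary.lm warn; the zero SEs are still meaningful
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  names(se) <- c("intercept", "height_exponent", "weight_exponent",
                 "female_offset")
  allometric_model(intercept = unname(cf[1]), height_exponent = unname(cf[2]),
                   weight_exponent = unname(cf[3]),
                   female_offset = unname(cf[4]),
                   ref_height_cm = mh, ref_weight_kg = mw,
                   r_squared = max(0, min(1, 1 - wss_res / wss_tot)),
                   n_fit = n, residual_sd = sqrt(wss_res / sum(w)), se = se)
}

#' Apply an allometric model as a normalized index
#'
#' Rescales a circumference to the model's reference height and weight:
#' \code{circumference * (H/ref)^(-a) * (W/ref)^(-b)} where \code{a}, \code{b}
#' are the fitted height/weight exponents.  At the reference body size the
#' index equals the raw circumference.
#'
#' @param model An \code{"allometric_model"}.
#' @param circumference,height_cm,weight_kg Positive measurements (cm, cm, kg);
#'   vectors are recycled by the usual rules.
#' @return Normalized circumference in cm.
#' @export
apply_allometric_index <- function(model, circumference, height_cm, weight_kg) {
  stopifnot(inherits(model, "allometric_model"))
  check_positive(circumference, "circumference")
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  circumference *
    (height_cm / model$ref_height_cm)^(-model$height_exponent) *
    (weight_kg  / model$ref_weight_kg)^(-model$weight_exponent)
}

#' Hip index (HI)
#'
#' Hip circumference normalized to a reference height and weight via the
#' exponents of the hip allometry regression:
#' \eqn{HI = HC (H/166)^{0.310} (W/73)^{-0.482}} under the default
#' [hip_model_nhanes()] model.  HI is constructed to be statistically
#' independent of height, BMI and ABSI.
#'
#' @inheritParams apply_allometric_index
#' @param hip_cm Hip circumference in cm.
#' @param model Allometric model to apply (default the published hip model).
#' @return HI in cm.
#' @export
compute_hi <- function(hip_cm, height_cm, weight_kg,
                       model = hip_model_nhanes()) {
  apply_allometric_index(model, hip_cm, height_cm, weight_kg)
}

#' @export
print.allometric_model <- function(x, ...) {
  cat("Allometric circumference model\n")
  cat(sprintf("  log C = %.4f %+.4f log H %+.4f log W %+.4f female\n",
              x$intercept, x$height_exponent, x$weight_exponent,
              x$female_offset))
  cat(sprintf("  reference body size: %g cm, %g kg\n",
              x$ref_height_cm, x$ref_weight_kg))
  if (!is.na(x$r_squared))
    cat(sprintf("  R-squared %.4f; n = %s\n", x$r_squared,
                format(x$n_fit)))
  invisible(x)
}

#' Serialize / restore an allometric model as JSON
#'
#' @param model An \code{"allometric_model"}.
#' @param path File path.
#' @return \code{read_allometric_model} returns the restored model;
#'   \code{write_allometric_model} returns \code{path} invisibly.
#' @export
write_allometric_model <- function(model, path) {
  stopifnot(inherits(model, "allometric_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_allometric_model
#' @export
read_allometric_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  allometric_model(x$intercept, x$height_exponent, x$weight_exponent,
                   x$female_offset, x$ref_height_cm, x$ref_weight_kg,
                   r_squared = x$r_squared %||% NA_real_,
                   n_fit = x$n_fit %||% NA_integer_,
                   residual_sd = x$residual_sd %||% NA_real_,
                   se = if (!is.null(x$se)) unlist(x$se))
}
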