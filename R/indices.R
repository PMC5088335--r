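#' @keywords internal
check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("field '", field, "' must be strictly positive and finite",
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Body mass index
#'
#' BMI = weight / height^2 with weight in kg and height in metres; height is
#' accepted in cm and converted internally.
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(height_cm, weight_kg) {
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  weight_kg / (height_cm / 100)^2
}

#' A body shape index (ABSI)
#'
#' ABSI = WC / (BMI^(2/3) H^(1/2)) with waist circumference WC and height H in
#' metres, so the numeric value carries units m^(11/6) kg^(-2/3).  ABSI
#' expresses waist circumference relative to height and weight and is
#' approximately uncorrelated with height and BMI.
#'
#' @param waist_cm Waist circumference in cm.
#' @inheritParams compute_bmi
#' @return ABSI in m^(11/6) kg^(-2/3).
#' @export
compute_absi <- function(waist_cm, height_cm, weight_kg) {
  check_positive(waist_cm, "waist_cm")
  bmi <- compute_bmi(height_cm, weight_kg)
  (waist_cm / 100) / (bmi^(2 / 3) * (height_cm / 100)^(1 / 2))
}

#' Waist-to-hip ratio
#'
#' @param waist_cm,hip_cm Circumferences in cm.
#' @return Dimensionless WC/HC.
#' @export
compute_whr <- function(waist_cm, hip_cm) {
  check_positive(waist_cm, "waist_cm")
  check_positive(hip_cm, "hip_cm")
  waist_cm / hip_cm
}

#' Eligibility gate for cohort records
#'
#' Single explicit exclusion filter applied before any fitting: drops records
#' that are pregnant, under 18 years of age, or have missing/nonpositive/
#' nonfinite height, weight, waist or hip measurements.  Exclusion counts are
#' attached as the \code{"exclusions"} attribute.
#'
#' @param records Cohort data frame in the standard schema.
#' @return The eligible subset, with an \code{"exclusions"} attribute (named
#'   integer vector).
#' @export
filter_eligible <- function(records) {
  stopifnot(is.data.frame(records))
  meas <- c("height_cm", "weight_kg", "waist_cm", "hip_cm")
  bad_meas <- rep(FALSE, nrow(records))
  for (m in intersect(meas, names(records))) {
    v <- records[[m]]
    bad_meas <- bad_meas | !is.finite(v) | v <= 0
  }
  preg <- if ("pregnant" %in% names(records))
    !is.na(records$pregnant) & records$pregnant == 1 else FALSE
  minor <- !is.finite(records$age_years) | records$age_years < 18
  drop <- bad_meas | preg | minor
  out <- records[!drop, , drop = FALSE]
  attr(out, "exclusions") <- c(
    pregnant = sum(preg & !bad_meas & !minor),
    under_18 = sum(minor),
    invalid_measurement = sum(bad_meas & !minor & !(preg & !bad_meas)),
    total = sum(drop))
  out
}

#' Derive the index panel for a cohort
#'
#' Computes height, BMI, ABSI, HI and WHR for every record, carrying the
#' demographic and survival columns through.  The hip index uses the supplied
#' allometric model (published NHANES coefficients by default).
#'
#' @param records Cohort data frame (already gated or not; the eligibility
#'   gate is applied).
#' @param hip_model \code{"allometric_model"} used for HI.
#' @return Data frame with the original columns plus \code{height},
#'   \code{bmi}, \code{absi}, \code{hi} and \code{whr}.
#' @export
compute_index_panel <- function(records, hip_model = hip_model_nhanes()) {
  records <- filter_eligible(records)
  records$height <- records$height_cm
  records$bmi  <- compute_bmi(records$height_cm, records$weight_kg)
  records$absi <- compute_absi(records$waist_cm, records$height_cm,
                               records$weight_kg)
  records$hi   <- compute_hi(records$hip_cm, records$height_cm,
                             records$weight_kg, model = hip_model)
  records$whr  <- compute_whr(records$waist_cm, records$hip_cm)
  records
}
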