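#' Default synthetic-cohort configuration
#'
#' Study conditions for the seeded cohort generator: a US-style adult cohort
#' with correlated lognormal height and weight, hip and waist circumferences
#' generated from power-law (allometric) models with sex offsets and lognormal
#' noise, and survival times from a Gompertz baseline hazard on the age
#' timescale multiplied by exponentiated component risk functions of the four
#' index z scores, with administrative censoring after a fixed cap.
#'
#' The anthropometric defaults are calibrated so that cohort medians fall in
#' published US interquartile bands (height median ~166 cm, weight ~73 kg),
#' the hip allometry uses the published NHANES coefficients, and the waist
#' allometry exponents (-5/6, 2/3) make the ABSI analogue independent of
#' height and BMI by construction.  Hazard components default to the
#' qualitative shapes seen in US cohorts: U-shaped in BMI (minimum half an SD
#' below the median) and HI, nearly linear in ABSI, weakly decreasing in
#' height.
#'
#' @param n Cohort size.
#' @param seed Integer RNG seed (Mersenne-Twister).
#' @return A \code{"generator_config"} list; see the vignette for the meaning
#'   and units of every field.
#' @export
default_config <- function(n = 20000, seed = 1) {
  structure(list(
    config_version = 1L,
    n = as.integer(n),
    seed = as.integer(seed),
    rng_kind = "Mersenne-Twister",
    female_fraction = 0.51,
    black_fraction = 0.11,
    entry_age_range = c(18, 80),
    # log-height N(mean_sex, sd); cm
    log_height = list(mean_male = log(173), mean_female = log(160),
                      sd = 0.041),
    # log-weight given centred log-height; kg
    log_weight = list(intercept_male = log(78), intercept_female = log(68),
                      slope = 2.0, sd = 0.17),
    # circumference power laws: C in cm, H in metres, W in kg
    hip = list(intercept = 2.658, height_exponent = -0.310,
               weight_exponent = 0.482, female_offset = 0.083,
               noise_sd = 0.03),
    waist = list(intercept = log(95) + (5 / 6) * log(1.73) -
                   (2 / 3) * log(78),
                 height_exponent = -5 / 6, weight_exponent = 2 / 3,
                 female_offset = -0.06, noise_sd = 0.055),
    hazard = hazard_spec(),
    followup_cap_years = 20,
    age_bin_width = 5,
    sample_weights = "unit"), class = "generator_config")
}

#' Hazard specification for the synthetic generator
#'
#' Gompertz baseline hazard \code{a exp(b t)} on the age timescale, log-linear
#' sex/race adjusters, and additive component risk functions of the four index
#' z scores (each linear with a slope, or quadratic with a curvature and a
#' location of minimum).
#'
#' @param gompertz_a Baseline hazard at age 0 (1/years).
#' @param gompertz_b Exponential ageing rate (1/years).
#' @param beta_female,beta_black Log hazard ratios of the adjusters.
#' @param components Named list (height, bmi, absi, hi) of component
#'   functions, each \code{list(type = "linear", slope =)} or
#'   \code{list(type = "quadratic", curvature =, minimum =)}.
#' @return A \code{"hazard_spec"} list.
#' @export
hazard_spec <- function(gompertz_a = 3e-5, gompertz_b = 0.09,
                        beta_female = -0.4, beta_black = 0.2,
                        components = list(
                          height = list(type = "linear", slope = -0.05),
                          bmi = list(type = "quadratic", curvature = 0.12,
                                     minimum = -0.5),
                          absi = list(type = "linear", slope = 0.15),
                          hi = list(type = "quadratic", curvature = 0.08,
                                    minimum = 0))) {
  stopifnot(gompertz_a > 0, gompertz_b >= 0)
  for (cmp in components)
    if (cmp$type == "quadratic" && cmp$curvature < 0)
      stop("quadratic component curvature must be nonnegative")
  structure(list(gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 beta_female = beta_female, beta_black = beta_black,
                 components = components), class = "hazard_spec")
}

#' Evaluate a component risk function
#'
#' @param component One element of \code{hazard_spec()$components}.
#' @param z Z-score vector.
#' @return Log hazard ratio contribution.
#' @export
component_log_hr <- function(component, z) {
  switch(component$type,
         linear = component$slope * z,
         quadratic = component$curvature * (z - component$minimum)^2,
         stop("unknown component type: ", component$type))
}

#' @keywords internal
validate_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with(config, {
    if (n < 1) stop("config field 'n' must be >= 1")
    if (female_fraction < 0 || female_fraction > 1)
      stop("config field 'female_fraction' must lie in [0, 1]")
    if (black_fraction < 0 || black_fraction > 1)
      stop("config field 'black_fraction' must lie in [0, 1]")
    for (fld in c("log_height", "log_weight", "hip", "waist")) {
      sd <- get(fld)[[grep("sd$", names(get(fld)), value = TRUE)[1]]]
      if (!is.numeric(sd) || sd < 0)
        stop("config field '", fld, "' has invalid sd")
    }
    if (followup_cap_years <= 0)
      stop("config field 'followup_cap_years' must be positive")
  })
  invisible(config)
}

#' Generate anthropometric records
#'
#' Draws sex and race by the configured fractions, entry ages uniformly,
#' height and weight from sex-specific correlated lognormal distributions,
#' and hip and waist circumferences from the configured allometric power laws
#' with lognormal noise.  Deterministic given \code{config$seed}.
#'
#' @param config A [default_config()]-style \code{"generator_config"}.
#' @return Cohort data frame in the standard schema, with
#'   \code{followup_years} and \code{died} unset (see [generate_survival()]).
#' @export
generate_anthropometry <- function(config = default_config()) {
  validate_config(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed, kind = config$rng_kind)
  n <- config$n
  female <- as.integer(stats::runif(n) < config$female_fraction)
  race_black <- as.integer(stats::runif(n) < config$black_fraction)
  age <- stats::runif(n, config$entry_age_range[1], config$entry_age_range[2])
  lh_mu <- ifelse(female == 1, config$log_height$mean_female,
                  config$log_height$mean_male)
  lh <- stats::rnorm(n, lh_mu, config$log_height$sd)
  lw_mu <- ifelse(female == 1, config$log_weight$intercept_female,
                  config$log_weight$intercept_male) +
    config$log_weight$slope * (lh - lh_mu)
  lw <- stats::rnorm(n, lw_mu, config$log_weight$sd)
  lh_m <- lh - log(100)   # circumference power laws take height in metres
  lhip <- config$hip$intercept + config$hip$height_exponent * lh_m +
    config$hip$weight_exponent * lw + config$hip$female_offset * female +
    stats::rnorm(n, 0, config$hip$noise_sd)
  lwaist <- config$waist$intercept + config$waist$height_exponent * lh_m +
    config$waist$weight_exponent * lw +
    config$waist$female_offset * female +
    stats::rnorm(n, 0, config$waist$noise_sd)
  sw <- if (identical(config$sample_weights, "lognormal"))
    stats::rlnorm(n, 0, 0.5) else rep(1, n)
  data.frame(subject_id = sprintf("S%06d", seq_len(n)),
             female = female, race_black = race_black, age_years = age,
             height_cm = exp(lh), weight_kg = exp(lw),
             waist_cm = exp(lwaist), hip_cm = exp(lhip),
             sample_weight = sw, followup_years = NA_real_,
             died = NA_integer_, pregnant = 0L)
}

#' Attach survival outcomes to a generated cohort
#'
#' Z-scores the four indices against the generated cohort's own reference
#' statistics, forms the log hazard ratio as the sum of the configured
#' component functions plus sex/race terms, and samples a death age by
#' inverse transform from the Gompertz proportional-hazards survival function
#' conditional on survival to the entry age (the integrated Gompertz hazard
#' has a closed-form inverse).  Deaths after \code{followup_cap_years} are
#' administratively censored at the cap.
#'
#' @param records Cohort from [generate_anthropometry()].
#' @param hazard A [hazard_spec()].
#' @param config The generator configuration (for the follow-up cap, age bin
#'   width and seed; survival sampling uses \code{seed + 1}).
#' @return \code{records} with \code{followup_years} and \code{died} filled
#'   in, plus attribute \code{"true_log_hr"} (the generating linear
#'   predictor, adjusters excluded) and \code{"z_panel"} (the self-referenced
#'   z scores used by the hazard layer).
#' @export
generate_survival <- function(records, hazard = default_config()$hazard,
                              config = default_config()) {
  stopifnot(inherits(hazard, "hazard_spec"))
  panel <- compute_index_panel(records)
  stats_tab <- estimate_reference_stats(panel,
                                        age_bin_width = config$age_bin_width,
                                        use_sample_weights = FALSE)
  panel <- zscore_cohort(panel, stats_tab, clamp_age = TRUE)
  true_lhr <- rep(0, nrow(panel))
  for (idx in names(hazard$components))
    true_lhr <- true_lhr +
      component_log_hr(hazard$components[[idx]], panel[[paste0("z_", idx)]])
  lp <- true_lhr + hazard$beta_female * panel$female +
    hazard$beta_black * panel$race_black

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed + 1L, kind = config$rng_kind)
  u <- stats::runif(nrow(panel))
  a <- hazard$gompertz_a * exp(lp)
  b <- hazard$gompertz_b
  t0 <- panel$age_years
  # S(t | t0) = exp(-(a/b) (e^{bt} - e^{bt0})); solve S = u for t
  death_age <- if (b > 0)
    log(exp(b * t0) - b * log(u) / a) / b
  else
    t0 - log(u) / a
  cap <- config$followup_cap_years
  died <- as.integer(death_age - t0 <= cap)
  followup <- pmin(death_age - t0, cap)
  out <- records[match(panel$subject_id, records$subject_id), , drop = FALSE]
  out$followup_years <- followup
  out$died <- died
  rownames(out) <- NULL
  attr(out, "true_log_hr") <- true_lhr
  attr(out, "z_panel") <- panel[, grep("^z_", names(panel), value = TRUE)]
  out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_anthropometry()] followed by
#' [generate_survival()].
#'
#' @inheritParams generate_anthropometry
#' @return Cohort data frame with survival outcomes and the attributes set by
#'   [generate_survival()].
#' @export
generate_cohort <- function(config = default_config()) {
  generate_survival(generate_anthropometry(config),
                    hazard = config$hazard, config = config)
}

#' Calibrate hip log-noise SD to a target population R-squared
#'
#' Under the generator, the linear predictor of the hip allometry,
#' \code{a log H + b log W + c f}, has a closed-form variance (normal mixture
#' over sex).  This solves for the residual SD that makes the population
#' R-squared of the log-log hip regression equal \code{target_r2}.
#'
#' @param config A \code{"generator_config"}.
#' @param target_r2 Desired population R-squared in (0, 1).
#' @return The config with \code{hip$noise_sd} replaced.
#' @export
calibrate_hip_noise <- function(config = default_config(), target_r2) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  p <- config$female_fraction
  a <- config$hip$height_exponent
  b <- config$hip$weight_exponent
  cc <- config$hip$female_offset
  sH <- config$log_height$sd
  sW <- config$log_weight$sd
  slope <- config$log_weight$slope
  # per sex s: lp = const_s + (a + b*slope) (lnH - mu_s) + b eps_W
  var_within <- (a + b * slope)^2 * sH^2 + b^2 * sW^2
  mean_m <- a * config$log_height$mean_male +
    b * config$log_weight$intercept_male
  mean_f <- a * config$log_height$mean_female +
    b * config$log_weight$intercept_female + cc
  var_between <- p * (1 - p) * (mean_f - mean_m)^2
  var_lp <- var_within + var_between
  config$hip$noise_sd <- sqrt(var_lp * (1 / target_r2 - 1))
  config
}
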