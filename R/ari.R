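#' Build an anthropometric risk index (ARI) model
#'
#' Full pipeline on a source cohort: fit the hip allometry, derive the index
#' panel, estimate age/sex reference statistics, z-score the four indices
#' (height, BMI, ABSI, HI), fit one penalized-spline Cox model per index
#' (each adjusted for sex and race, smoothing selected by AICc), center the
#' four log-hazard-ratio curves, and record the cohort distribution of their
#' sum.  A subject's ARI is the sum of the four curve values at the subject's
#' z scores, with positive values denoting above-average combined risk.
#'
#' @param cohort Cohort data frame in the standard schema.
#' @param spec A [spline_spec()] shared by the four component fits.
#' @param age_bin_width Reference age-bin width in years (default 5).
#' @param use_sample_weights Use sample weights throughout (default TRUE).
#' @param hip_from_cohort Refit the hip allometry on this cohort (default);
#'   otherwise use the published NHANES model.
#' @param provenance Free-text metadata list stored with the model.
#' @return An \code{"ari_model"}: reference stats, four risk curves, the hip
#'   model, ARI standardization constants, the component \code{"cox_fit"}s
#'   and provenance.
#' @export
build_ari_model <- function(cohort, spec = spline_spec(),
                            age_bin_width = 5, use_sample_weights = TRUE,
                            hip_from_cohort = TRUE,
                            provenance = list(source = "unspecified")) {
  cohort <- filter_eligible(cohort)
  hip_model <- if (hip_from_cohort)
    fit_allometric_model(cohort, "hip_cm",
                         use_sample_weights = use_sample_weights)
  else hip_model_nhanes()
  panel <- compute_index_panel(cohort, hip_model = hip_model)
  stats_tab <- estimate_reference_stats(panel, age_bin_width = age_bin_width,
                                        use_sample_weights = use_sample_weights)
  panel <- zscore_cohort(panel, stats_tab, clamp_age = TRUE)
  surv <- survival_data(panel, use_sample_weights = use_sample_weights)

  indices <- c("height", "bmi", "absi", "hi")
  curves <- list()
  fits <- list()
  for (idx in indices) {
    res <- tryCatch(
      fit_cox_spline(surv, panel[[paste0("z_", idx)]], spec = spec),
      error = function(e)
        stop("ARI build failed for index '", idx, "': ",
             conditionMessage(e), call. = FALSE))
    curves[[idx]] <- res$curve
    fits[[idx]] <- res$fit
  }
  ari <- rep(0, nrow(panel))
  for (idx in indices)
    ari <- ari + evaluate_risk_curve(curves[[idx]],
                                     panel[[paste0("z_", idx)]])
  w <- surv$weight / sum(surv$weight)
  ari_mean <- sum(w * ari)
  ari_sd <- sqrt(sum(w * (ari - ari_mean)^2))
  if (ari_sd <= 0) stop("degenerate ARI distribution (zero variance)")
  structure(list(reference_stats = stats_tab, curves = curves,
                 hip_model = hip_model, ari_mean = ari_mean,
                 ari_sd = ari_sd, spline_spec = spec,
                 component_fits = fits,
                 use_sample_weights = use_sample_weights,
                 provenance = provenance), class = "ari_model")
}

#' Score subjects with an ARI model
#'
#' Computes the four index z scores against the model's reference statistics
#' (ages outside the covered range are clamped to the nearest bin when
#' \code{clamp_age = TRUE}), evaluates each centered risk curve by exact
#' basis evaluation (clamped outside its validity range), and sums the
#' contributions.
#'
#' @param model An \code{"ari_model"}.
#' @param records Cohort data frame (one or more subjects).
#' @param indices Indices to include; the default is all four, and
#'   \code{c("height", "bmi", "absi")} gives the truncated ARI for cohorts
#'   without hip measurements.
#' @param clamp_age Clamp out-of-range ages (default TRUE, needed for
#'   transfer to older cohorts).
#' @return Data frame with \code{subject_id}, \code{z_<index>} and
#'   \code{contrib_<index>} columns, \code{ari} (sum of contributions, log
#'   hazard units) and \code{ari_standardized}
#'   ((ari - ari_mean) / ari_sd on the source cohort's scale).
#' @export
compute_ari <- function(model, records,
                        indices = c("height", "bmi", "absi", "hi"),
                        clamp_age = TRUE) {
  stopifnot(inherits(model, "ari_model"))
  bad <- setdiff(indices, names(model$curves))
  if (length(bad)) stop("no risk curve for index: ", paste(bad, collapse = ", "))
  need <- c("height_cm", "weight_kg", "waist_cm", "hip_cm", "age_years",
            "female")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("scoring error, missing fields: ", paste(miss, collapse = ", "))
  panel <- compute_index_panel(records, hip_model = model$hip_model)
  panel <- zscore_cohort(panel, model$reference_stats, index_names = indices,
                         clamp_age = clamp_age)
  out <- data.frame(subject_id = panel$subject_id %||%
                      sprintf("row%d", seq_len(nrow(panel))))
  ari <- rep(0, nrow(panel))
  for (idx in indices) {
    z <- panel[[paste0("z_", idx)]]
    contrib <- evaluate_risk_curve(model$curves[[idx]], z)
    out[[paste0("z_", idx)]] <- z
    out[[paste0("contrib_", idx)]] <- as.numeric(contrib)
    ari <- ari + contrib
  }
  out$ari <- as.numeric(ari)
  out$ari_standardized <- (out$ari - model$ari_mean) / model$ari_sd
  out
}

#' Linear Cox fit of the standardized ARI
#'
#' Scores the cohort with the model and fits a Cox model with standardized
#' ARI as the single linear covariate plus sex/race adjusters, reporting the
#' hazard ratio per SD of ARI.
#'
#' @param cohort Cohort data frame.
#' @param model An \code{"ari_model"}.
#' @param use_sample_weights Weight the Cox fit (default: as the model was
#'   built).
#' @param indices Indices summed into the score (see [compute_ari()]).
#' @return A \code{"cox_fit"}.
#' @export
fit_ari_linear <- function(cohort, model,
                           use_sample_weights = model$use_sample_weights,
                           indices = c("height", "bmi", "absi", "hi")) {
  cohort <- filter_eligible(cohort)
  scores <- compute_ari(model, cohort, indices = indices)
  surv <- survival_data(cohort, use_sample_weights = use_sample_weights)
  fit_cox_linear(surv, scores$ari_standardized)
}

#' Compare the ARI against single-index models on a cohort
#'
#' Fits, on the given cohort: the linear standardized-ARI model, a linear and
#' a penalized-spline (nonlinear) Cox model for each of the four index z
#' scores (z-scored against the ARI model's reference statistics, i.e. the
#' source cohort's normals), and the adjuster-only baseline; returns the AIC
#' difference table.  With the model's own source cohort this is the
#' in-sample comparison; with an external cohort it evaluates transfer.
#'
#' @param model An \code{"ari_model"}.
#' @param cohort Cohort data frame to evaluate on.
#' @param use_sample_weights Weight the Cox fits.
#' @param component_fits Optional named list of precomputed nonlinear
#'   \code{"cox_fit"}s for the four indices (reused from the model build when
#'   evaluating on the source cohort); when \code{NULL} they are refitted on
#'   \code{cohort}.
#' @return List with elements \code{table} (see [delta_aic_table()]) and
#'   \code{fits} (named list of \code{"cox_fit"}s).
#' @export
compare_index_models <- function(model, cohort,
                                 use_sample_weights = model$use_sample_weights,
                                 component_fits = NULL) {
  stopifnot(inherits(model, "ari_model"))
  cohort <- filter_eligible(cohort)
  panel <- compute_index_panel(cohort, hip_model = model$hip_model)
  panel <- zscore_cohort(panel, model$reference_stats, clamp_age = TRUE)
  surv <- survival_data(panel, use_sample_weights = use_sample_weights)
  scores <- compute_ari(model, cohort)

  fits <- list()
  fits[["ARI (linear)"]] <- fit_cox_linear(surv, scores$ari_standardized)
  for (idx in c("height", "bmi", "absi", "hi")) {
    z <- panel[[paste0("z_", idx)]]
    lab <- c(height = "H", bmi = "BMI", absi = "ABSI", hi = "HI")[[idx]]
    fits[[paste0(lab, " (linear)")]] <- fit_cox_linear(surv, z)
    fits[[paste0(lab, " (nonlinear)")]] <-
      if (!is.null(component_fits)) component_fits[[idx]]
      else fit_cox_spline(surv, z, spec = model$spline_spec)$fit
  }
  fits[["None"]] <- fit_cox_linear(surv, NULL)
  list(table = delta_aic_table(fits), fits = fits)
}

#' Evaluate transfer of an ARI model to an external cohort
#'
#' Scores cohort B with a model built on cohort A (A's reference statistics,
#' curves and hip model; out-of-range ages and z scores clamped), then fits
#' the linear-ARI model and B's own single-index models on B and returns the
#' comparison table.
#'
#' @param model An \code{"ari_model"} built on the source cohort.
#' @param cohort External cohort data frame.
#' @param use_sample_weights Weight the Cox fits on the external cohort
#'   (default FALSE: external cohorts are typically equal-weighted).
#' @return See [compare_index_models()].
#' @export
transfer_evaluate <- function(model, cohort, use_sample_weights = FALSE) {
  compare_index_models(model, cohort,
                       use_sample_weights = use_sample_weights)
}

#' Serialize / restore an ARI model as JSON
#'
#' A single JSON document bundling reference statistics, the four risk curves
#' (basis representation plus redundant evaluation grid), the hip allometry
#' model, ARI standardization constants and provenance; round-trip stable.
#' Component Cox fits are not serialized.
#'
#' @param model An \code{"ari_model"}.
#' @param path File path.
#' @return \code{read_ari_model} returns the restored model.
#' @export
write_ari_model <- function(model, path) {
  stopifnot(inherits(model, "ari_model"))
  stats_df <- as.data.frame(model$reference_stats)
  stats_df$age_hi <- as.character(stats_df$age_hi)   # JSON has no Inf
  doc <- list(
    format = "anthrorisk_ari_model",
    version = 1L,
    reference_stats = stats_df,
    age_bin_edges = as.character(attr(model$reference_stats,
                                      "age_bin_edges")),
    curves = lapply(model$curves, risk_curve_to_list),
    hip_model = unclass(model$hip_model),
    ari_mean = model$ari_mean, ari_sd = model$ari_sd,
    spline_spec = unclass(model$spline_spec),
    use_sample_weights = model$use_sample_weights,
    provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_ari_model
#' @export
read_ari_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "anthrorisk_ari_model"))
    stop("not an ARI model file: ", path)
  stats_df <- x$reference_stats
  for (col in c("age_lo", "age_hi", "mean", "sd", "effective_n"))
    stats_df[[col]] <- as.numeric(stats_df[[col]])
  stats_tab <- structure(stats_df,
                         class = c("reference_stats", "data.frame"),
                         age_bin_edges = as.numeric(unlist(x$age_bin_edges)),
                         sd_denom = "unknown")
  hm <- x$hip_model
  curves <- lapply(x$curves, risk_curve_from_list)
  structure(list(
    reference_stats = stats_tab, curves = curves,
    hip_model = allometric_model(hm$intercept, hm$height_exponent,
                                 hm$weight_exponent, hm$female_offset,
                                 hm$ref_height_cm, hm$ref_weight_kg,
                                 r_squared = hm$r_squared %||% NA_real_,
                                 n_fit = hm$n_fit %||% NA_integer_,
                                 residual_sd = hm$residual_sd %||% NA_real_,
                                 se = if (!is.null(hm$se)) unlist(hm$se)),
    ari_mean = x$ari_mean, ari_sd = x$ari_sd,
    spline_spec = do.call(spline_spec, x$spline_spec[
      c("basis_degree", "n_interior_knots", "knot_placement",
        "penalty_order", "lambda_grid")]),
    component_fits = NULL,
    use_sample_weights = x$use_sample_weights %||% TRUE,
    provenance = x$provenance), class = "ari_model")
}

#' @export
print.ari_model <- function(x, ...) {
  cat("Anthropometric risk index (ARI) model\n")
  cat(sprintf("  indices: %s\n", paste(names(x$curves), collapse = ", ")))
  cat(sprintf("  hip allometry exponents: height %.3f, weight %.3f\n",
              x$hip_model$height_exponent, x$hip_model$weight_exponent))
  cat(sprintf("  ARI cohort mean %.4f, SD %.4f\n", x$ari_mean, x$ari_sd))
  invisible(x)
}
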