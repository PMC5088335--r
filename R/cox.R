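#' Survival data on the age timescale
#'
#' Builds entry/exit ages from a cohort data frame: subjects enter risk sets
#' at their examination age (delayed entry / left truncation) and leave at
#' \code{age_years + followup_years}, with \code{died} marking an event.
#'
#' @param cohort Cohort data frame in the standard schema.
#' @param use_sample_weights Carry \code{sample_weight} as case weights.
#' @return Data frame with columns \code{entry_age}, \code{exit_age},
#'   \code{event}, \code{weight}, \code{female}, \code{race_black}.
#' @export
survival_data <- function(cohort, use_sample_weights = TRUE) {
  stopifnot(all(c("age_years", "followup_years", "died") %in% names(cohort)))
  if (any(cohort$followup_years <= 0))
    stop("followup_years must be positive (exit age must exceed entry age)")
  data.frame(entry_age = cohort$age_years,
             exit_age = cohort$age_years + cohort$followup_years,
             event = as.integer(cohort$died),
             weight = if (use_sample_weights && "sample_weight" %in%
                          names(cohort)) cohort$sample_weight
                      else rep(1, nrow(cohort)),
             female = cohort$female,
             race_black = cohort$race_black)
}

#' Cox partial log-likelihood with delayed entry
#'
#' Weighted partial log-likelihood on the age timescale with Efron correction
#' for tied event ages, for a fixed linear predictor.  The risk set at event
#' age t is \{i : entry < t <= exit\}.
#'
#' @param surv Survival data from [survival_data()].
#' @param linear_predictor Numeric vector, one value per subject.
#' @return Log partial likelihood (scalar).
#' @export
partial_log_likelihood <- function(surv, linear_predictor) {
  stopifnot(nrow(surv) == length(linear_predictor))
  if (sum(surv$event) == 0)
    stop("undefined likelihood: no events in the data")
  res <- cox_loglik_cpp(surv$entry_age, surv$exit_age,
                        as.integer(surv$event), surv$weight,
                        as.numeric(linear_predictor),
                        matrix(0, nrow(surv), 0), FALSE)
  res$loglik
}

#' @keywords internal
cox_newton <- function(surv, X, penalty = NULL, lambda = 0, init = NULL,
                       max_iter = 50, tol = 1e-9) {
  p <- ncol(X)
  beta <- init %||% rep(0, p)
  if (is.null(penalty)) penalty <- matrix(0, p, p)
  pen_obj <- function(ll, b) ll - 0.5 * lambda * drop(t(b) %*% penalty %*% b)
  ev <- function(b) cox_loglik_cpp(surv$entry_age, surv$exit_age,
                                   as.integer(surv$event), surv$weight,
                                   drop(X %*% b), X, TRUE)
  cur <- ev(beta)
  obj <- pen_obj(cur$loglik, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- cur$grad - lambda * drop(penalty %*% beta)
    Ipen <- cur$info + lambda * penalty
    step <- tryCatch(solve(Ipen, g), error = function(e) {
      solve(Ipen + diag(1e-8 * (1 + diag(Ipen))), g)
    })
    halve <- 0
    repeat {
      cand <- beta + step
      new <- ev(cand)
      nobj <- pen_obj(new$loglik, cand)
      if (is.finite(nobj) && nobj >= obj - 1e-12) break
      step <- step / 2
      halve <- halve + 1
      if (halve > 30) break
    }
    if (halve > 30) break
    improve <- nobj - obj
    beta <- cand; cur <- new; obj <- nobj
    if (abs(improve) < tol * (abs(obj) + 1)) { converged <- TRUE; break }
  }
  list(beta = beta, loglik = cur$loglik, grad = cur$grad, info = cur$info,
       n_events = cur$n_events, n_events_weighted = cur$n_events_weighted,
       converged = converged, iter = iter,
       separated = any(abs(beta) > 15))
}

#' @keywords internal
aicc_value <- function(loglik, df_eff, n_events) {
  aic <- -2 * loglik + 2 * df_eff
  if (n_events <= df_eff + 1) {
    warning("AICc correction undefined (n_events <= df_eff + 1); returning Inf")
    return(Inf)
  }
  aic + 2 * df_eff * (df_eff + 1) / (n_events - df_eff - 1)
}

#' Corrected Akaike information criterion of a Cox fit
#'
#' \code{AICc = -2 loglik + 2 df + 2 df (df + 1) / (n_events - df - 1)},
#' using the effective degrees of freedom and the number of events as the
#' sample-size term.  Returns \code{Inf} with a warning when the correction is
#' undefined (\code{n_events <= df + 1}).
#'
#' @param fit A \code{"cox_fit"}.
#' @return AICc (scalar).
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  aicc_value(fit$log_partial_likelihood, fit$df_eff, fit$n_events)
}

#' @keywords internal
new_cox_fit <- function(form, coefficients, covariance, loglik, null_loglik,
                        df_eff, n_events, n, surv, lp, hr_per_sd = NULL,
                        lambda = NA_real_, converged = TRUE,
                        separated = FALSE) {
  aic <- -2 * loglik + 2 * df_eff
  fit <- structure(list(
    form = form,
    coefficients = coefficients,
    covariance = covariance,
    log_partial_likelihood = loglik,
    null_log_partial_likelihood = null_loglik,
    df_eff = df_eff,
    aic = aic,
    aicc = if (n_events > df_eff + 1) aicc_value(loglik, df_eff, n_events)
           else Inf,
    n_events = n_events,
    n = n,
    hr_per_sd = hr_per_sd,
    lambda = lambda,
    converged = converged,
    separated = separated,
    concordance = concordance_index(surv, lp),
    r_squared = explained_variation_value(loglik, null_loglik, n_events),
    linear_predictor = lp), class = "cox_fit")
  fit
}

#' Linear Cox proportional-hazards fit on the age timescale
#'
#' Maximizes the weighted Efron partial likelihood by Newton-Raphson for a
#' single linear covariate (an index z score) plus unpenalized adjusters.
#' In this model the death rate changes by a constant factor per SD change in
#' the index; that factor is reported as \code{hr_per_sd} with a Wald 95\% CI.
#'
#' @param surv Survival data from [survival_data()].
#' @param z Covariate vector (index z scores), or \code{NULL} for the
#'   adjuster-only baseline model.
#' @param adjusters Columns of \code{surv} entered unpenalized (default sex
#'   and race indicators).
#' @return A \code{"cox_fit"} with coefficients, covariance, log partial
#'   likelihood, AIC/AICc, hazard ratio per SD, concordance and an
#'   explained-variation measure.
#' @export
fit_cox_linear <- function(surv, z, adjusters = c("female", "race_black")) {
  X <- build_design(surv, z, adjusters,
                    zname = if (is.null(z)) character(0) else "z")
  if (!is.null(z) && stats::var(z) == 0)
    stop("covariate has zero variance")
  null_ll <- null_loglik(surv)
  fit <- cox_newton(surv, X)
  if (!fit$converged)
    stop("Cox Newton-Raphson failed to converge after ", fit$iter,
         " iterations (max |beta| = ", signif(max(abs(fit$beta)), 3), ")")
  if (fit$separated)
    warning("possible separation: a coefficient is very large")
  V <- solve(fit$info)
  dimnames(V) <- list(colnames(X), colnames(X))
  hr <- NULL
  if (!is.null(z)) {
    se <- sqrt(V[1, 1])
    hr <- c(hr = exp(fit$beta[1]),
            lo95 = exp(fit$beta[1] - 1.959964 * se),
            hi95 = exp(fit$beta[1] + 1.959964 * se))
  }
  cf <- stats::setNames(fit$beta, colnames(X))
  new_cox_fit(if (is.null(z)) "baseline" else "linear", cf, V,
              fit$loglik, null_ll, df_eff = ncol(X),
              n_events = fit$n_events, n = nrow(surv), surv = surv,
              lp = drop(X %*% fit$beta), hr_per_sd = hr,
              separated = fit$separated)
}

#' @keywords internal
build_design <- function(surv, z, adjusters, zname = "z") {
  cols <- list()
  if (!is.null(z)) {
    stopifnot(length(z) == nrow(surv), all(is.finite(z)))
    cols$z <- z
  }
  for (a in adjusters) cols[[a]] <- surv[[a]]
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(0, nrow(surv), 0)
  colnames(X) <- c(zname, adjusters)
  X
}

#' @keywords internal
null_loglik <- function(surv) {
  partial_log_likelihood(surv, rep(0, nrow(surv)))
}

#' @keywords internal
explained_variation_value <- function(loglik, null_loglik, n_events) {
  r2 <- 1 - exp(2 * (null_loglik - loglik) / n_events)
  if (r2 < 0) {
    warning("model log-likelihood below null; clamping R^2 to 0")
    r2 <- 0
  }
  r2
}

#' Explained variation of a Cox model
#'
#' \code{R^2 = 1 - exp(2 (l_null - l_model) / m)} with \code{m} the number of
#' events: a likelihood-ratio based measure of the proportion of variation in
#' mortality explained by the predictors.  This is one of several such
#' measures in use and is labelled as a declared convention in outputs.
#'
#' @param fit A \code{"cox_fit"}.
#' @param null_fit Optional \code{"cox_fit"} to use as the null; by default
#'   the empty (no-covariate) model stored in \code{fit}.
#' @return R^2 in [0, 1].
#' @export
explained_variation <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  ll0 <- if (is.null(null_fit)) fit$null_log_partial_likelihood
         else null_fit$log_partial_likelihood
  if (!is.null(null_fit) && null_fit$n_events != fit$n_events)
    stop("fits are not comparable: different event counts")
  explained_variation_value(fit$log_partial_likelihood, ll0, fit$n_events)
}

#' Concordance index with delayed entry
#'
#' Harrell-type concordance: the weighted fraction of comparable subject pairs
#' for which the subject modeled to be at greater risk died sooner.  A pair is
#' comparable when one subject dies at an age at which the other is still at
#' risk (accounting for delayed entry); predictor ties count 1/2.
#'
#' @param surv Survival data from [survival_data()].
#' @param linear_predictor Risk score vector (higher = riskier).
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(surv, linear_predictor) {
  stopifnot(nrow(surv) == length(linear_predictor))
  res <- concordance_cpp(surv$entry_age, surv$exit_age,
                         as.integer(surv$event), surv$weight,
                         as.numeric(linear_predictor))
  if (res$comparable == 0)
    stop("undefined concordance: no comparable pairs")
  (res$concordant + 0.5 * res$tied) / res$comparable
}

#' AIC difference table for a set of Cox fits
#'
#' Computes \eqn{\Delta_i = AIC_i - \min AIC} across fits of the same cohort
#' and outcome, ordered by decreasing skill (increasing \eqn{\Delta_i});
#' \eqn{\Delta_i > 6} flags models performing significantly worse than the
#' best model.
#'
#' @param fits Named list of \code{"cox_fit"} objects.
#' @return Data frame with columns \code{predictor}, \code{form},
#'   \code{hr_per_sd}, \code{ci_lo}, \code{ci_hi}, \code{aic},
#'   \code{delta_i}, \code{significantly_worse}, \code{r2}, \code{c}.
#' @export
delta_aic_table <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  ne <- vapply(fits, function(f) f$n_events, numeric(1))
  if (length(unique(ne)) != 1L)
    stop("fits are not comparable: different event counts (",
         paste(unique(ne), collapse = ", "), ")")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  hr <- t(vapply(fits, function(f)
    if (is.null(f$hr_per_sd)) c(NA_real_, NA_real_, NA_real_)
    else f$hr_per_sd, numeric(3)))
  out <- data.frame(predictor = names(fits),
                    form = vapply(fits, function(f) f$form, character(1)),
                    hr_per_sd = hr[, 1], ci_lo = hr[, 2], ci_hi = hr[, 3],
                    aic = aic, delta_i = aic - min(aic),
                    r2 = vapply(fits, function(f) f$r_squared, numeric(1)),
                    c = vapply(fits, function(f) f$concordance, numeric(1)),
                    row.names = NULL)
  out$significantly_worse <- out$delta_i > 6
  out[order(out$delta_i), ]
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s), age timescale\n", x$form))
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  if (!is.null(x$hr_per_sd))
    cat(sprintf("  HR per SD = %.3f (%.3f-%.3f)\n", x$hr_per_sd[1],
                x$hr_per_sd[2], x$hr_per_sd[3]))
  cat(sprintf("  loglik = %.3f, df_eff = %.2f, AIC = %.2f, AICc = %.2f\n",
              x$log_partial_likelihood, x$df_eff, x$aic, x$aicc))
  cat(sprintf("  concordance = %.4f, R^2 = %.4f (likelihood-ratio measure)\n",
              x$concordance, x$r_squared))
  invisible(x)
}
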