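#' Penalized spline specification
#'
#' Cubic B-spline basis over the observed z range with interior knots at
#' quantiles (or uniformly spaced), and a difference penalty on the spline
#' coefficients.  The penalty is built from divided differences with respect
#' to the Greville abscissae, so its null space contains exactly the
#' polynomials of degree \code{penalty_order - 1} in z regardless of knot
#' spacing; with \code{penalty_order = 2} the heavy-penalty limit of the fit
#' is therefore the linear Cox model.
#'
#' @param basis_degree Spline degree (default 3, cubic).
#' @param n_interior_knots Number of interior knots (default 10).
#' @param knot_placement \code{"quantile"} (default) or \code{"uniform"}.
#' @param penalty_order Order of the difference penalty (default 2).
#' @param lambda_grid Positive smoothing weights to search (default 41
#'   log-spaced points from 1e-2 to 1e8; the top of the grid is deep enough
#'   into the penalty-dominated regime that the fit there coincides with the
#'   linear Cox model).
#' @return A \code{"spline_spec"} list.
#' @export
spline_spec <- function(basis_degree = 3, n_interior_knots = 10,
                        knot_placement = c("quantile", "uniform"),
                        penalty_order = 2,
                        lambda_grid = 10^seq(-2, 8, length.out = 41)) {
  knot_placement <- match.arg(knot_placement)
  stopifnot(basis_degree >= 1, n_interior_knots >= penalty_order,
            penalty_order >= 1, all(lambda_grid > 0))
  structure(list(basis_degree = basis_degree,
                 n_interior_knots = n_interior_knots,
                 knot_placement = knot_placement,
                 penalty_order = penalty_order,
                 lambda_grid = sort(lambda_grid)),
            class = "spline_spec")
}

#' @keywords internal
make_spline_basis <- function(z, spec) {
  rng <- range(z)
  if (diff(rng) <= 0)
    stop("covariate range too narrow for knot placement")
  interior <- if (spec$knot_placement == "quantile") {
    probs <- seq_len(spec$n_interior_knots) / (spec$n_interior_knots + 1)
    as.numeric(stats::quantile(z, probs, names = FALSE, type = 7))
  } else {
    seq(rng[1], rng[2],
        length.out = spec$n_interior_knots + 2)[-c(1, spec$n_interior_knots + 2)]
  }
  interior <- sort(interior)
  if (any(diff(c(rng[1], interior, rng[2])) <= 0))
    stop("covariate range too narrow for knot placement (duplicate knots)")
  ord <- spec$basis_degree + 1
  knots <- c(rep(rng[1], ord), interior, rep(rng[2], ord))
  K <- length(knots) - ord
  # Greville abscissae: knot averages; a B-spline with coefficients linear in
  # these sites reproduces a linear function of z
  greville <- vapply(seq_len(K), function(j)
    mean(knots[(j + 1):(j + spec$basis_degree)]), numeric(1))
  list(knots = knots, degree = spec$basis_degree, K = K,
       greville = greville, valid_range = rng)
}

#' @keywords internal
eval_basis <- function(basis, z) {
  z <- pmin(pmax(z, basis$valid_range[1]), basis$valid_range[2])
  splines::splineDesign(basis$knots, z, ord = basis$degree + 1)
}

# order-q divided-difference matrix w.r.t. sites xi: D %*% theta gives the
# q-th divided differences, zero iff theta is a degree-(q-1) polynomial in xi
#' @keywords internal
divided_diff_matrix <- function(xi, order) {
  K <- length(xi)
  D <- diag(K)
  for (q in seq_len(order)) {
    Kq <- K - q
    Dq <- matrix(0, Kq, Kq + 1)
    for (j in seq_len(Kq)) {
      h <- xi[j + q] - xi[j]
      Dq[j, j] <- -1 / h
      Dq[j, j + 1] <- 1 / h
    }
    D <- Dq %*% D
  }
  # scale comparable to ordinary differences on a unit-spaced grid
  mean(diff(xi))^order * D
}

#' Penalized-spline Cox fit with AICc smoothing selection
#'
#' Models the log hazard ratio as a smooth function of an index z score:
#' cubic B-spline basis, difference penalty on the spline coefficients,
#' unpenalized sex/race adjusters.  For each smoothing weight on the grid the
#' penalized partial likelihood is maximized by Newton-Raphson (warm-started
#' along the grid); the effective degrees of freedom are
#' \code{trace[(H + lambda P)^{-1} H]} with \code{H} the unpenalized observed
#' information, and the grid point minimizing AICc is selected.  The constant
#' direction of the basis (unidentifiable in a Cox model) is projected out;
#' the returned curve is centered to weighted mean zero over the fitting
#' cohort.
#'
#' @inheritParams fit_cox_linear
#' @param spec A [spline_spec()].
#' @return List with elements \code{fit} (a \code{"cox_fit"}) and
#'   \code{curve} (a \code{"risk_curve"}).
#' @export
fit_cox_spline <- function(surv, z, spec = spline_spec(),
                           adjusters = c("female", "race_black")) {
  stopifnot(inherits(spec, "spline_spec"), length(z) == nrow(surv),
            all(is.finite(z)))
  basis <- make_spline_basis(z, spec)
  B <- eval_basis(basis, z)
  K <- basis$K
  # remove the constant direction: B-splines sum to one, so coefficient
  # vector 1 spans the unidentifiable constant; Z spans its complement
  Z <- qr.Q(qr(cbind(rep(1, K), diag(K))))[, 2:K, drop = FALSE]
  Xs <- B %*% Z
  A <- as.matrix(build_design(surv, NULL, adjusters, zname = character(0)))
  X <- cbind(Xs, A)
  p <- ncol(X)
  Dmat <- divided_diff_matrix(basis$greville, spec$penalty_order)
  P <- matrix(0, p, p)
  P[seq_len(K - 1), seq_len(K - 1)] <- t(Z) %*% crossprod(Dmat) %*% Z

  null_ll <- null_loglik(surv)
  best <- NULL
  init <- NULL
  any_conv <- FALSE
  for (lam in rev(spec$lambda_grid)) {   # heavy smoothing first: stable start
    fit <- cox_newton(surv, X, penalty = P, lambda = lam, init = init)
    if (!fit$converged) next
    any_conv <- TRUE
    init <- fit$beta
    Ipen <- fit$info + lam * P
    Vi <- tryCatch(solve(Ipen), error = function(e) NULL)
    if (is.null(Vi)) next
    df_eff <- sum(diag(Vi %*% fit$info))
    ac <- aicc_value(fit$loglik, df_eff, fit$n_events)
    if (is.null(best) || ac < best$aicc) {
      best <- list(fit = fit, lambda = lam, df_eff = df_eff, aicc = ac,
                   V = Vi)
    }
  }
  if (!any_conv)
    stop("penalized spline fit failed to converge for every lambda")

  fit <- best$fit
  cf <- stats::setNames(fit$beta, c(paste0("s", seq_len(K - 1)), adjusters))
  coefs <- drop(Z %*% fit$beta[seq_len(K - 1)])   # back to B-spline space
  w <- surv$weight / sum(surv$weight)
  offset <- sum(w * drop(B %*% coefs))
  curve <- new_risk_curve(basis = basis, coefficients = coefs,
                          centering_offset = offset,
                          Z = Z, V = best$V[seq_len(K - 1), seq_len(K - 1),
                                            drop = FALSE],
                          bbar = colSums(w * B))
  lp <- drop(X %*% fit$beta)
  cfit <- new_cox_fit("nonlinear", cf, best$V, fit$loglik, null_ll,
                      df_eff = best$df_eff, n_events = fit$n_events,
                      n = nrow(surv), surv = surv, lp = lp,
                      lambda = best$lambda, separated = fit$separated)
  list(fit = cfit, curve = curve)
}
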