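test_that("partial likelihood matches exhaustive risk-set enumeration", {
  set.seed(21)
  for (rep in 1:60) {
    d <- random_tiny_surv(sample(2:6, 1))
    lp <- round(rnorm(nrow(d)), 1)  # rounding creates predictor ties
    expect_equal(partial_log_likelihood(d, lp),
                 bf_partial_loglik(d$entry_age, d$exit_age, d$event,
                                   d$weight, lp),
                 tolerance = 1e-12)
  }
})

test_that("partial likelihood basic identities hold", {
  # single event, risk set of size one: log(1) = 0
  d1 <- data.frame(entry_age = 50, exit_age = 55, event = 1L, weight = 1,
                   female = 0, race_black = 0)
  expect_equal(partial_log_likelihood(d1, 0.7), 0)
  # translation invariance
  set.seed(22)
  d <- random_tiny_surv(6)
  lp <- rnorm(6)
  expect_equal(partial_log_likelihood(d, lp),
               partial_log_likelihood(d, lp + 5.3), tolerance = 1e-10)
  # no events -> undefined
  d0 <- d; d0$event <- 0L
  expect_error(partial_log_likelihood(d0, lp), "no events")
})

test_that("linear fit agrees with an independent Cox implementation", {
  skip_if_not_installed("survival")
  set.seed(23)
  n <- 300
  d <- data.frame(age_years = runif(n, 30, 70), female = rbinom(n, 1, .5),
                  race_black = rbinom(n, 1, .2),
                  sample_weight = sample(c(1, 2, .5), n, TRUE),
                  followup_years = sample(1:8, n, TRUE),
                  died = rbinom(n, 1, .5))
  z <- rnorm(n)
  surv <- survival_data(d)
  mine <- fit_cox_linear(surv, z)
  ref <- survival::coxph(
    survival::Surv(age_years, age_years + followup_years, died) ~
      z + female + race_black,
    data = cbind(d, z = z), weights = sample_weight, ties = "efron")
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(mine$log_partial_likelihood, ref$loglik[2], tolerance = 1e-8)
  expect_equal(mine$null_log_partial_likelihood, ref$loglik[1],
               tolerance = 1e-8)
  expect_equal(sqrt(diag(mine$covariance)), sqrt(diag(vcov(ref))),
               tolerance = 0.05)  # efron-with-weights variance conventions differ
})

test_that("3-subject fit matches grid search of the brute-force likelihood", {
  # death order alternates across z so the likelihood has an interior max
  d <- data.frame(entry_age = c(40, 42, 45), exit_age = c(49, 50, 53),
                  event = c(1L, 1L, 1L), weight = c(1, 1, 1),
                  female = c(0, 0, 0), race_black = c(0, 0, 0))
  z <- c(0.5, -1, 1.2)
  fit <- fit_cox_linear(d, z, adjusters = character(0))
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, function(b)
    bf_partial_loglik(d$entry_age, d$exit_age, d$event, d$weight, b * z),
    numeric(1))
  expect_equal(unname(fit$coefficients[1]), grid[which.max(ll)],
               tolerance = 2e-3)
})

test_that("null covariates give hazard ratios near one", {
  fx <- fixture_panel(4000, 2)
  set.seed(24)
  zperm <- sample(fx$panel$z_bmi)   # breaks any covariate-outcome link
  fit <- fit_cox_linear(fx$surv, zperm)
  expect_lt(abs(log(fit$hr_per_sd["hr"])), 0.1)
  expect_true(fit$hr_per_sd["lo95"] < 1 && fit$hr_per_sd["hi95"] > 1)
})

test_that("linear slope recovery across seeded replicates", {
  # cohort with a pure linear log-hazard in the ABSI z score
  ok <- 0L
  for (s in 1:10) {
    cfg <- default_config(n = 8000, seed = 300 + s)
    cfg$hazard <- hazard_spec(components = list(
      height = list(type = "linear", slope = 0),
      bmi = list(type = "linear", slope = 0),
      absi = list(type = "linear", slope = 0.25),
      hi = list(type = "linear", slope = 0)))
    coh <- generate_cohort(cfg)
    panel <- compute_index_panel(coh)
    panel <- zscore_cohort(panel, estimate_reference_stats(panel))
    fit <- fit_cox_linear(survival_data(panel), panel$z_absi)
    se <- sqrt(fit$covariance[1, 1])
    ok <- ok + (abs(fit$coefficients[1] - 0.25) <= 3 * se)
  }
  expect_gte(ok, 9L)
})

test_that("AICc follows its defining arithmetic", {
  expect_equal(aicc_fake(-100, 4, 100), 208.421, tolerance = 1e-3)
  expect_equal(aicc_fake(-77.7, 0, 10), 155.4)  # df 0: plain -2 loglik
  # aicc decreases to aic as events grow
  vals <- vapply(c(20, 50, 200, 1e4), function(m) aicc_fake(-100, 4, m),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[4], 208, tolerance = 0.01)
})

test_that("delta-AIC tables rank, flag and stay order-invariant", {
  fx <- fixture_panel(4000, 2)
  f1 <- fit_cox_linear(fx$surv, fx$panel$z_absi)
  f2 <- fit_cox_linear(fx$surv, fx$panel$z_bmi)
  f0 <- fit_cox_linear(fx$surv, NULL)
  tab <- delta_aic_table(list(absi = f1, bmi = f2, none = f0))
  expect_equal(tab$delta_i[1], 0)
  expect_true(all(diff(tab$delta_i) >= 0))
  tab2 <- delta_aic_table(list(none = f0, bmi = f2, absi = f1))
  a <- tab[order(tab$predictor), -1]; rownames(a) <- NULL
  b <- tab2[order(tab2$predictor), -1]; rownames(b) <- NULL
  expect_equal(b, a, tolerance = 1e-12)

  # synthetic aic values: {100, 103} -> no flag; {50, 57} -> flagged
  fa <- f1; fb <- f1
  fa$aic <- 100; fb$aic <- 103
  t1 <- delta_aic_table(list(a = fa, b = fb))
  expect_equal(t1$delta_i, c(0, 3))
  expect_false(any(t1$significantly_worse))
  fb$aic <- 57; fa$aic <- 50
  t2 <- delta_aic_table(list(a = fa, b = fb))
  expect_equal(t2$delta_i, c(0, 7))
  expect_identical(t2$significantly_worse, c(FALSE, TRUE))

  # mismatched cohorts are not comparable
  fy <- fit_cox_linear(fixture_panel(2000, 9)$surv,
                       fixture_panel(2000, 9)$panel$z_bmi)
  expect_error(delta_aic_table(list(a = f1, b = fy)), "not comparable")
})

test_that("concordance matches brute-force pair enumeration and bounds", {
  set.seed(25)
  for (rep in 1:60) {
    d <- random_tiny_surv(sample(3:6, 1))
    lp <- round(rnorm(nrow(d)), 1)
    bf <- bf_concordance(d$entry_age, d$exit_age, d$event, d$weight, lp)
    if (bf["den"] == 0) {
      expect_error(concordance_index(d, lp), "no comparable")
    } else {
      ci <- concordance_index(d, lp)
      expect_equal(ci, unname(bf["num"] / bf["den"]), tolerance = 1e-12)
      expect_gte(ci, 0); expect_lte(ci, 1)
    }
  }
})

test_that("concordance handles perfect ordering, constancy and reversal", {
  d <- data.frame(entry_age = c(0, 0, 0), exit_age = c(1, 2, 3),
                  event = c(1L, 1L, 1L), weight = 1, female = 0,
                  race_black = 0)
  expect_equal(concordance_index(d, c(3, 2, 1)), 1)      # riskiest dies first
  expect_equal(concordance_index(d, c(1, 1, 1)), 0.5)    # all ties
  expect_equal(concordance_index(d, c(3, 1, 2)), 2 / 3)  # one discordant pair
  # reversal maps C to 1 - C on tie-free data
  set.seed(26)
  dd <- random_tiny_surv(6); dd$exit_age <- dd$exit_age + runif(6, 0, .4)
  lp <- rnorm(6)
  expect_equal(concordance_index(dd, -lp), 1 - concordance_index(dd, lp),
               tolerance = 1e-12)
})

test_that("explained variation follows the likelihood-ratio formula", {
  expect_equal(1 - exp(2 * (-500 - -490) / 400), 0.04877, tolerance = 1e-4)
  fx <- fixture_panel(4000, 2)
  f0 <- fit_cox_linear(fx$surv, NULL)
  f1 <- fit_cox_linear(fx$surv, fx$panel$z_absi)
  r2_manual <- 1 - exp(2 * (f0$log_partial_likelihood -
                            f1$log_partial_likelihood) / f1$n_events)
  expect_equal(explained_variation(f1, f0), r2_manual, tolerance = 1e-12)
  # fit equal to its own null reference gives 0
  expect_equal(explained_variation(f0, f0), 0)
  # monotone in the model log-likelihood
  lls <- seq(f0$log_partial_likelihood, f1$log_partial_likelihood,
             length.out = 5)
  r2s <- 1 - exp(2 * (f0$log_partial_likelihood - lls) / f1$n_events)
  expect_true(all(diff(r2s) > 0))
})

test_that("a covariate independent of outcome rarely worsens AIC by more than 6", {
  ok <- 0L
  fx <- fixture_panel(2000, 9)
  f0 <- fit_cox_linear(fx$surv, NULL)
  set.seed(27)
  for (rep in 1:20) {
    zperm <- sample(fx$panel$z_hi)
    f1 <- fit_cox_linear(fx$surv, zperm)
    ok <- ok + ((f1$aic - f0$aic) < 6)
  }
  expect_gte(ok, 18L)
})
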