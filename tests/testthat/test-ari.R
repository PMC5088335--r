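# building an ARI model is the expensive step; share one across tests
ari_fixture <- function() {
  if (is.null(.fixture_env$ari)) {
    coh <- fixture_cohort(6000, 8)
    .fixture_env$ari <- list(
      cohort = coh,
      model = build_ari_model(coh, provenance = list(source = "synthetic")))
  }
  .fixture_env$ari
}

test_that("ARI is exactly the sum of its per-index contributions", {
  fx <- ari_fixture()
  scores <- compute_ari(fx$model, fx$cohort[1:500, ])
  manual <- scores$contrib_height + scores$contrib_bmi +
    scores$contrib_absi + scores$contrib_hi
  expect_identical(scores$ari, manual)
  # truncated ARI: three contributions only
  tr <- compute_ari(fx$model, fx$cohort[1:500, ],
                    indices = c("height", "bmi", "absi"))
  expect_identical(tr$ari, tr$contrib_height + tr$contrib_bmi +
                     tr$contrib_absi)
  expect_null(tr$contrib_hi)
})

test_that("the source cohort's standardized ARI has weighted mean 0 and SD 1", {
  fx <- ari_fixture()
  scores <- compute_ari(fx$model, fx$cohort)
  w <- fx$cohort$sample_weight / sum(fx$cohort$sample_weight)
  m <- sum(w * scores$ari_standardized)
  s2 <- sum(w * (scores$ari_standardized - m)^2)
  expect_lt(abs(m), 1e-10)
  expect_equal(s2, 1, tolerance = 1e-10)
})

test_that("scoring uses exact basis evaluation, not grid interpolation", {
  fx <- ari_fixture()
  rec <- fx$cohort[7, ]
  scores <- compute_ari(fx$model, rec)
  exact <- evaluate_risk_curve(fx$model$curves$bmi, scores$z_bmi)
  expect_equal(scores$contrib_bmi, as.numeric(exact), tolerance = 1e-15)
  # dense grid interpolation is close but not what is used
  cur <- fx$model$curves$bmi
  interp <- approx(cur$z_grid, cur$log_hr, xout = scores$z_bmi)$y
  expect_lt(abs(scores$contrib_bmi - interp), 1e-3)
})

test_that("identity curves make ARI the plain sum of z scores", {
  fx <- ari_fixture()
  model <- fx$model
  # replace each fitted curve with the function f(z) = z: coefficients at
  # the Greville abscissae reproduce a linear function exactly
  for (idx in names(model$curves)) {
    cur <- model$curves[[idx]]
    K <- length(cur$coefficients)
    greville <- vapply(seq_len(K), function(j)
      mean(cur$knots[(j + 1):(j + cur$degree)]), numeric(1))
    cur$coefficients <- greville
    cur$centering_offset <- 0
    cur$log_hr <- evaluate_risk_curve(cur, cur$z_grid)
    model$curves[[idx]] <- cur
  }
  scores <- compute_ari(model, fx$cohort[1:200, ])
  expect_equal(scores$ari,
               scores$z_height + scores$z_bmi + scores$z_absi + scores$z_hi,
               tolerance = 1e-10)
})

test_that("a cohort with no anthropometric effects yields a flat, uninformative ARI", {
  cfg <- default_config(n = 6000, seed = 16)
  cfg$hazard <- hazard_spec(components = list(
    height = list(type = "linear", slope = 0),
    bmi = list(type = "linear", slope = 0),
    absi = list(type = "linear", slope = 0),
    hi = list(type = "linear", slope = 0)))
  coh <- generate_cohort(cfg)
  model <- build_ari_model(coh)
  expect_lt(model$ari_sd, 0.15)
  fit <- fit_ari_linear(coh, model)
  expect_lt(fit$concordance, 0.62)   # sex/race carry some signal; ARI adds ~none
  f0 <- fit_cox_linear(survival_data(coh), NULL)
  expect_lt(fit$aic - f0$aic, 6)
})

test_that("rebuilding with an identical seed gives byte-identical serialization", {
  cfg <- default_config(n = 3000, seed = 17)
  m1 <- build_ari_model(generate_cohort(cfg))
  m2 <- build_ari_model(generate_cohort(cfg))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_ari_model(m1, p1); write_ari_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("ARI models round-trip through JSON with identical scores", {
  fx <- ari_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_ari_model(fx$model, path)
  m2 <- read_ari_model(path)
  s1 <- compute_ari(fx$model, fx$cohort[1:300, ])
  s2 <- compute_ari(m2, fx$cohort[1:300, ])
  expect_equal(s2, s1, tolerance = 1e-9)
  expect_error(read_ari_model(withr::local_tempfile(lines = "{}",
                                                    fileext = ".json")),
               "not an ARI model")
})

test_that("self-transfer reproduces the in-sample ARI fit", {
  fx <- ari_fixture()
  insample <- fit_ari_linear(fx$cohort, fx$model)
  res <- transfer_evaluate(fx$model, fx$cohort, use_sample_weights = TRUE)
  trans <- res$fits[["ARI (linear)"]]
  expect_equal(trans$coefficients, insample$coefficients, tolerance = 1e-10)
  expect_equal(trans$aic, insample$aic, tolerance = 1e-8)
  expect_true(all(c("ARI (linear)", "BMI (nonlinear)", "None") %in%
                    res$table$predictor))
})

test_that("scoring reports missing measurement fields by name", {
  fx <- ari_fixture()
  rec <- fx$cohort[1:2, ]
  rec$hip_cm <- NULL
  expect_error(compute_ari(fx$model, rec), "hip_cm")
})
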