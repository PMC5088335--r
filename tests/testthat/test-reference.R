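make_panel <- function(values, female = 0, age = 40, w = 1) {
  n <- length(values)
  data.frame(age_years = rep(age, n), female = rep(female, n),
             sample_weight = rep(w, length.out = n), bmi = values)
}

test_that("per-cell weighted means and SDs match hand arithmetic", {
  st <- estimate_reference_stats(make_panel(c(1, 2, 3)), "bmi",
                                 age_bin_width = 67)
  cell <- st[st$sex == 0 & st$effective_n > 0, ]
  expect_equal(cell$mean, 2)
  expect_equal(cell$sd, 0.8165, tolerance = 1e-4)  # population convention

  st2 <- estimate_reference_stats(make_panel(c(1, 4), w = c(2, 1)), "bmi",
                                  age_bin_width = 67)
  cell2 <- st2[st2$sex == 0 & st2$effective_n > 0, ]
  expect_equal(cell2$mean, 2.0)  # (2*1 + 1*4) / 3

  # sample (n-1 style) convention on unit weights
  st3 <- estimate_reference_stats(make_panel(c(1, 2, 3)), "bmi",
                                  age_bin_width = 67, sd_denom = "sample")
  expect_equal(st3$sd[st3$effective_n > 0 & st3$sex == 0], 1)
})

test_that("constant cells are flagged degenerate at z-scoring time", {
  st <- estimate_reference_stats(make_panel(c(7, 7, 7)), "bmi",
                                 age_bin_width = 67)
  cell <- st[st$sex == 0 & st$effective_n > 0, ]
  expect_equal(cell$mean, 7)
  expect_equal(cell$sd, 0)
  expect_error(zscore_transform(c(bmi = 7), 40, 0, st), "degenerate")
})

test_that("empty cohorts and unknown indices are rejected", {
  expect_error(estimate_reference_stats(make_panel(numeric(0))),
               "insufficient|empty")
  expect_error(estimate_reference_stats(make_panel(1:5), "nope"),
               "unknown index")
  expect_error(zscore_transform(c(bmi = 25), 15, 0,
                                estimate_reference_stats(make_panel(1:5),
                                                         "bmi")),
               "outside")
})

test_that("z transform matches hand arithmetic and clamping works", {
  panel <- make_panel(rnorm(50, 26, 4))
  st <- estimate_reference_stats(panel, "bmi", age_bin_width = 67)
  cell <- st[st$sex == 0 & st$effective_n > 0, ]
  expect_equal(unname(zscore_transform(c(bmi = cell$mean), 40, 0, st)), 0)
  expect_equal(unname(zscore_transform(c(bmi = cell$mean + cell$sd),
                                       40, 0, st)), 1)
  z <- (28 - cell$mean) / cell$sd
  expect_equal(unname(zscore_transform(c(bmi = 28), 40, 0, st)), z)
  # hand example: value 28, mean 26, sd 4 -> 0.5
  st$mean[st$effective_n > 0 & st$sex == 0] <- 26
  st$sd[st$effective_n > 0 & st$sex == 0] <- 4
  expect_equal(unname(zscore_transform(c(bmi = 28), 40, 0, st)), 0.5)
  # clamping: age beyond the covered range reuses the terminal bin
  expect_equal(zscore_transform(c(bmi = 28), 99, 0, st, clamp_age = TRUE),
               zscore_transform(c(bmi = 28), 40, 0, st))
})

test_that("re-z-scoring the source cohort gives weighted mean 0 and SD 1 per cell", {
  fx <- fixture_panel(4000, 2)
  panel <- fx$panel
  edges <- attr(fx$stats, "age_bin_edges")
  bin <- findInterval(panel$age_years, edges)
  for (idx in c("bmi", "hi")) {
    z <- panel[[paste0("z_", idx)]]
    for (sex in 0:1) for (b in unique(bin)) {
      sel <- panel$female == sex & bin == b
      if (sum(sel) < 2) next
      w <- panel$sample_weight[sel] / sum(panel$sample_weight[sel])
      m <- sum(w * z[sel])
      s2 <- sum(w * (z[sel] - m)^2)
      expect_lt(abs(m), 1e-10)
      expect_lt(abs(s2 - 1), 1e-10)
    }
  }
})

test_that("percentile conversion is correct and monotone", {
  expect_equal(z_to_percentile(0), 50)
  expect_equal(z_to_percentile(1.959964), 97.5, tolerance = 1e-6)
  zs <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(z_to_percentile(zs)) > 0))
  # empirical method: counting fraction below
  expect_equal(z_to_percentile(0.5, "empirical", reference_z = c(-1, 0, 1)),
               66.67, tolerance = 1e-2)
  emp <- z_to_percentile(zs, "empirical", reference_z = rnorm(500))
  expect_true(all(diff(emp) >= 0))
  expect_error(z_to_percentile(0.5, "empirical"), "reference")
})

test_that("correlation matrices are symmetric with unit diagonal; constants give NA", {
  fx <- fixture_panel(4000, 2)
  r <- correlation_matrix(fx$panel, c("height", "bmi", "hi"))
  expect_equal(diag(r), c(height = 1, bmi = 1, hi = 1))
  expect_equal(r, t(r))
  p2 <- fx$panel
  p2$collin <- 2 * p2$bmi + 1
  expect_equal(correlation_matrix(p2, c("bmi", "collin"))[1, 2], 1,
               tolerance = 1e-12)
  p2$flat <- 5
  rc <- correlation_matrix(p2, c("bmi", "flat"))
  expect_true(is.na(rc["bmi", "flat"]))
  expect_error(correlation_matrix(fx$panel[1:2, ], "bmi"), "insufficient")
})

test_that("z-scored indices decorrelate while raw circumferences stay correlated", {
  fx <- fixture_panel()   # default 20k cohort
  zr <- correlation_matrix(fx$panel, c("height", "bmi", "absi", "hi"),
                           on_zscores = TRUE)
  expect_true(all(abs(zr[upper.tri(zr)]) < 0.1))
  raw <- correlation_matrix(fx$panel, c("weight_kg", "hip_cm", "waist_cm",
                                        "bmi"))
  expect_gt(raw["weight_kg", "hip_cm"], 0.7)
  expect_gt(raw["bmi", "waist_cm"], 0.7)
  # combined table: raw upper triangle, z lower triangle
  tab <- correlation_table(fx$panel, c("height", "bmi", "hi"))
  expect_equal(tab[1, 3], correlation_matrix(fx$panel,
                                             c("height", "bmi", "hi"))[1, 3])
  expect_equal(tab[3, 1], zr["hi", "height"], tolerance = 1e-12)
})

test_that("reference tables round-trip through CSV", {
  fx <- fixture_panel(4000, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_stats(fx$stats, path)
  st2 <- read_reference_stats(path)
  expect_equal(as.data.frame(st2), as.data.frame(fx$stats),
               tolerance = 1e-12, ignore_attr = TRUE)
})
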