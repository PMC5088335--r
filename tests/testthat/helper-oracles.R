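# Independent brute-force oracles used to check the Cox engine, plus
# memoised synthetic cohorts shared across test files.

# Exhaustive risk-set enumeration of the weighted Efron partial likelihood:
# risk sets are formed by explicit subsetting at every event age (no
# incremental bookkeeping, unlike the package implementation).
bf_partial_loglik <- function(entry, exit, event, weight, lp) {
  ll <- 0
  for (t in sort(unique(exit[event == 1]))) {
    D <- which(exit == t & event == 1)
    R <- which(entry < t & exit >= t)
    s0r <- sum(weight[R] * exp(lp[R]))
    s0d <- sum(weight[D] * exp(lp[D]))
    k <- length(D)
    mw <- mean(weight[D])
    ll <- ll + sum(weight[D] * lp[D])
    for (j in seq_len(k) - 1) ll <- ll - mw * log(s0r - (j / k) * s0d)
  }
  ll
}

# Brute-force pair enumeration of the delayed-entry concordance.
bf_concordance <- function(entry, exit, event, weight, lp) {
  num <- den <- 0
  n <- length(entry)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    t <- exit[i]
    for (j in seq_len(n)[-i]) {
      if (entry[j] >= t || exit[j] < t) next
      if (exit[j] == t && event[j] == 1) next
      w <- weight[i] * weight[j]
      den <- den + w
      if (lp[i] > lp[j]) num <- num + w
      else if (lp[i] == lp[j]) num <- num + w / 2
    }
  }
  c(num = num, den = den)
}

# Random tiny survival instance with tied ages, tied predictors and varied
# weights; guaranteed at least one event.
random_tiny_surv <- function(n = 6) {
  repeat {
    entry <- sample(0:3, n, replace = TRUE)
    exit <- entry + sample(1:4, n, replace = TRUE)
    event <- stats::rbinom(n, 1, 0.6)
    if (sum(event) >= 1) break
  }
  data.frame(entry_age = entry, exit_age = exit, event = event,
             weight = sample(c(0.5, 1, 2), n, replace = TRUE),
             female = stats::rbinom(n, 1, 0.5),
             race_black = stats::rbinom(n, 1, 0.2))
}

# Memoised cohorts (generation is deterministic; caching only saves time).
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(n = 20000, seed = 1, config = NULL) {
  key <- if (is.null(config)) paste0("c", n, "_", seed) else
    paste0("c", n, "_", seed, "_", digest_config(config))
  if (is.null(.fixture_env[[key]])) {
    cfg <- config %||% anthrorisk::default_config(n = n, seed = seed)
    .fixture_env[[key]] <- anthrorisk::generate_cohort(cfg)
  }
  .fixture_env[[key]]
}

digest_config <- function(config)
  substr(paste(unlist(config), collapse = "|"), 1, 200)

`%||%` <- function(a, b) if (is.null(a)) b else a

# one full ARI build on a default-condition cohort, memoised per seed; the
# ARI-superiority and transfer checks share these replicates
ari_replicate <- function(s) {
  key <- paste0("rep", s)
  if (is.null(.fixture_env[[key]])) {
    coh <- anthrorisk::generate_cohort(
      anthrorisk::default_config(n = 20000, seed = 500 + s))
    .fixture_env[[key]] <- list(cohort = coh,
                                model = anthrorisk::build_ari_model(coh))
  }
  .fixture_env[[key]]
}

# minimal stand-in object for exercising the AICc arithmetic directly
aicc_fake <- function(ll, df, m)
  anthrorisk::aicc(structure(list(log_partial_likelihood = ll, df_eff = df,
                                  n_events = m), class = "cox_fit"))

# Standard analysis pipeline on a cohort: cohort-fitted hip model, index
# panel, 5-year age/sex reference stats, z scores, survival frame.
fixture_panel <- function(n = 20000, seed = 1) {
  key <- paste0("p", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    coh <- fixture_cohort(n, seed)
    hip <- anthrorisk::fit_allometric_model(coh)
    panel <- anthrorisk::compute_index_panel(coh, hip_model = hip)
    stats_tab <- anthrorisk::estimate_reference_stats(panel)
    panel <- anthrorisk::zscore_cohort(panel, stats_tab)
    .fixture_env[[key]] <- list(cohort = coh, hip = hip, panel = panel,
                                stats = stats_tab,
                                surv = anthrorisk::survival_data(panel))
  }
  .fixture_env[[key]]
}
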