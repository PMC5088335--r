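# anthrorisk

Body measurements — height (H), weight (W), waist (WC) and hip (HC)
circumference — each predict mortality, but they are too strongly
correlated with one another to be combined naively.  `anthrorisk`
implements an allometric route around that problem for epidemiologists and
biostatisticians working with cohort data:

1. **Normalize.**  BMI = W/H² removes height from weight;
   ABSI = WC/(BMI^(2/3)·H^(1/2)) removes height and BMI from waist; and a
   **hip index**,

   HI = HC · (H/166 cm)^0.310 · (W/73 kg)^(−0.482),

   removes height and weight from hip circumference.  The HI exponents come
   from the log-log least-squares power law
   log HC = 2.658 − 0.310·log H + 0.482·log W + 0.083·f  (R² = 0.887),
   and `fit_allometric_model()` refits this regression on any cohort.
   After age- and sex-specific z-scoring, H, BMI, ABSI and HI are mutually
   nearly uncorrelated (|r| < 0.1).

2. **Estimate risk curves.**  Each index z score enters a Cox
   proportional-hazards model on the age timescale (delayed entry, Efron
   ties, case weights) with a penalized-spline log-hazard curve; the amount
   of smoothing is selected by AICc.  Sex and race are adjusted for
   throughout.

3. **Combine.**  The **anthropometric risk index (ARI)** of a subject is
   the sum of the four fitted log-hazard-ratio curves evaluated at the
   subject's z scores.  The fitted model (reference tables + curves + hip
   exponents) serializes to a single JSON document and can score external
   cohorts; Δi (AIC-difference), R² and concordance tables compare it
   against single-index models.

Because the survey microdata behind the published constants cannot be
redistributed, the package ships a seeded synthetic-cohort generator
(`generate_cohort()`) with realistic anthropometry, the published hip
power law, and Gompertz survival with known U-shaped/linear component
effects — so every step is testable end to end.

## Worked example

```r
library(anthrorisk)

coh <- generate_cohort(default_config(n = 20000, seed = 1))

# refit the hip power law on this cohort
m <- fit_allometric_model(coh)
m
#> Allometric circumference model
#>   log C = 2.6527 -0.3109 log H +0.4834 log W +0.0830 female
#>   reference body size: 166 cm, 74 kg
#>   R-squared 0.8960; n = 20000
```

The fitted exponents recover the published constants (−0.310, 0.482,
0.083) to well within sampling error.  Deriving indices, z-scoring and
fitting a linear hazard model for ABSI:

```r
panel <- compute_index_panel(coh, hip_model = m)
stats <- estimate_reference_stats(panel)        # sex x 5-year-age normals
panel <- zscore_cohort(panel, stats)
fit <- fit_cox_linear(survival_data(panel), panel$z_absi)
fit
#> Cox proportional-hazards fit (linear), age timescale
#>   n = 20000, events = 5388
#>   HR per SD = 1.118 (1.089-1.149)
#>   loglik = -43797.308, df_eff = 3.00, AIC = 87600.62, AICc = 87600.62
#>   concordance = 0.5674, R^2 = 0.0505 (likelihood-ratio measure)
```

Death rate rises by ~12% per SD of ABSI here (the generator's true slope
is 0.15 ≈ HR 1.16; attenuation reflects 20-year follow-up truncation).
Building and applying the combined index:

```r
model <- build_ari_model(coh)                   # four spline fits + normals
scores <- compute_ari(model, coh)               # per-subject ARI
head(scores[, c("subject_id", "ari", "ari_standardized")])
fit_ari_linear(coh, model)                      # HR per SD of ARI
write_ari_model(model, "ari_model.json")        # portable risk calculator
transfer_evaluate(model, other_cohort)$table    # delta-AIC comparison
```

Single measurements work directly:

```r
compute_bmi(170, 91.4)      #> 31.6 kg/m^2
compute_absi(120.5, 170, 91.4)  #> 0.0924
compute_hi(105.3, 170, 91.4)    #> 95.1 cm
z_to_percentile(1.96)       #> 97.5
```

A thin CLI covering the same pipeline (simulate / derive-index /
reference-stats / fit-risk / build-ari / score / transfer) is installed at
`inst/cli/anthrorisk`.

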