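---
title: "Methods: allometric indices, spline hazard curves and the combined risk index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometric indices, spline hazard curves and the combined risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Body mass index (BMI = W/H², kg/m²) expresses weight independently of
height; a body shape index (ABSI = WC / (BMI^(2/3) H^(1/2)), SI units)
expresses waist circumference independently of height and BMI.  Both are
instances of allometric normalization: regress the log of one measurement on
the logs of the others, and exponentiate the residual.  `anthrorisk`
implements this construction generally and applies it to hip circumference,
yielding a hip index

HI = HC · (H / 166 cm)^0.310 · (W / 73 kg)^(−0.482),

the hip circumference rescaled to a reference body size.  Because log HI is
an affine function of a least-squares residual, it is uncorrelated with
log H and log W in the fitting sample by construction, and after age/sex
z-scoring the four indices H, BMI, ABSI and HI are mutually nearly
independent — which is what makes their risk contributions addable.

The package then estimates how each index relates to all-cause mortality
and sums the fitted log-hazard-ratio curves into a single anthropometric
risk index (ARI).

## Allometric fitting

`fit_allometric_model()` runs weighted least squares of log circumference
(cm) on log height, log weight and a female indicator.  Height enters in
metres: that is the unit convention under which the published hip-model
intercept (2.658) reproduces hip circumferences near 100 cm at the reference
body size, and we keep it so that refitted intercepts are directly
comparable to that constant.  The exponents and the normalized index are
unit-invariant, so no other quantity depends on this choice.

The reference height and weight default to the weighted cohort means rounded
to whole cm/kg, matching the convention of the published model (166 cm,
73 kg); `round_reference = FALSE` keeps exact means.  Weighted R² is
1 − (weighted residual SS)/(weighted total SS about the weighted mean).
Exclusions (pregnancy, age under 18, nonpositive or missing measurements)
are applied by one explicit gate, `filter_eligible()`, whose counts are
attached to its result — never silently inside individual operations.

## Reference normalization

`estimate_reference_stats()` tabulates weighted means and SDs per sex and
age bin; z-scoring subtracts the cell mean and divides by the cell SD.
Choices made here, each exposed as an argument:

* **Bin width** — 5-year bins over ages 18–85 with a terminal open bin.
  The granularity of published reference tables varies; 5 years is fine
  enough to track adult age trends at feasible cell sizes.
* **SD convention** — population form (denominator = total weight), since a
  reference table describes a population, with a sample (n − 1) option.
* **Out-of-range ages** — an error by default; `clamp_age = TRUE` snaps to
  the nearest populated bin, which is required when applying one cohort's
  normals to an older cohort.
* **Percentiles** — `z_to_percentile()` defaults to the normal
  approximation 100·Φ(z); an empirical weighted-ECDF method is available
  when the reference cohort is at hand.
* **Empty cells** are never interpolated by default.

## Survival modeling

All hazard models use age as the timescale: a subject examined at age 50
and followed 20 years contributes to risk sets only on (50, 70].  This
delayed-entry (left-truncated) weighted Cox partial likelihood, with the
Efron correction for tied event ages, is implemented in compiled code; risk
sets are maintained incrementally over decreasing event ages.  Sample
weights enter as case weights; variance is model-based (no survey
cluster/robust correction).  Tie handling matches the weighted Efron
convention of standard survival software, which the test suite verifies
against an independent implementation; reported standard errors come from
the exact observed information of this likelihood.

**Linear fits** (`fit_cox_linear()`) report the hazard ratio per SD of the
index z score with a Wald 95% CI.  **Nonlinear fits** (`fit_cox_spline()`)
expand the z score in a cubic B-spline basis (10 interior knots at
covariate quantiles) with sex/race adjusters unpenalized, and maximize the
penalized partial likelihood ℓ(β) − (λ/2)·βᵀPβ by Newton–Raphson, warm
started from heavier smoothing.

Numerical choices worth knowing about:

* **Penalty** — second-order *divided* differences with respect to the
  B-spline Greville abscissae, not raw coefficient differences.  With
  quantile (hence unequal) knots, raw second differences do not annihilate
  linear functions; divided differences do, so the heavy-smoothing limit of
  the fit is exactly the linear Cox model.  With equally spaced knots the
  two coincide.
* **Identifiability** — a Cox model cannot estimate a constant, and the
  B-spline basis sums to one, so the constant coefficient direction is
  projected out before fitting.  Each returned curve is then centered so
  the weighted cohort-mean log hazard ratio is zero.
* **Smoothing selection** — λ is chosen from a log-spaced grid (10⁻² to
  10⁸, 41 points) by AICc, with effective degrees of freedom
  trace[(H + λP)⁻¹H] (H the unpenalized observed information) and the
  number of events as the AICc sample-size term.  The grid top is deep
  enough into the penalty-dominated regime that the fit there coincides
  with the linear model to ~10⁻⁴ in log HR at cohort sizes of tens of
  thousands; model selection never chooses it unless the data are truly
  linear.
* **Extrapolation** — curves are clamped at their boundary values outside
  the observed z range; scoring reports how many evaluations were clamped.
* **Initialization and randomness** — Newton starts at β = 0; nothing in
  fitting is stochastic, so rebuilding a model from the same cohort is
  byte-identical.

Model comparison follows the Δi convention: Δi = AICᵢ − min AIC across
models fitted to the same cohort, with Δi > 6 flagging decisively worse
models.  The explained-variation measure is R² = 1 − exp(2(ℓ₀ − ℓ)/m) with
m the number of events — one of several likelihood-ratio-based measures in
use, and labelled as a declared convention.  Concordance is Harrell's C
restricted to pairs comparable under delayed entry (the later-dying member
must be at risk at the earlier death age); predictor ties count 1/2.

## The combined index

`build_ari_model()` chains the steps: hip allometry → index panel →
reference stats → z scores → four penalized-spline fits → centered curves.
A subject's ARI is the *sum of the four curve values* at their z scores —
the sex/race adjuster coefficients of the component fits are deliberately
not part of the score (they re-enter as adjusters in downstream fits), since
the score is meant to capture anthropometric risk only.  Summing log hazard
ratios treats the four hazards as independent, which the z-score
decorrelation approximately justifies.  The ARI is reported raw (log-hazard
units, cohort-centered) and standardized by its weighted cohort SD, the
form in which "hazard ratio per SD of ARI" is estimated.  Each curve is
centered on its own fit; any residual nonzero mean of the sum is absorbed
into the stored `ari_mean`.  A truncated ARI (height + BMI + ABSI, for
settings without hip measurement) is available via the `indices` argument.

Transfer to an external cohort uses the *source* model end to end: source
reference statistics, source curves, source hip exponents; out-of-range
ages and z scores are clamped.  Whether external-cohort comparisons should
instead re-normalize with local z scores is a genuinely open choice; using
source normals throughout matches the intended use of a portable risk
calculator and is what `transfer_evaluate()` does.

## The synthetic cohort generator

No public survey microdata ship with the package; `generate_cohort()`
produces cohorts with the structure the analysis assumes, calibrated once:

* Sex (51% female) and race (11% black) as Bernoulli draws; entry ages
  uniform on 18–80.
* Log height normal per sex (male 173 cm, female 160 cm, log-sd 0.041);
  log weight conditionally normal given height (slope 2.0, log-sd 0.17,
  sex intercepts 78/68 kg), giving height–weight correlations near 0.5 and
  medians inside the published interquartile bands (~166 cm, ~73 kg).
* Hip circumference from the published power law (exponents −0.310/0.482,
  female offset 0.083) with log-noise sd 0.03, which puts the regression R²
  near its published value; `calibrate_hip_noise()` solves for the sd that
  hits a target population R² exactly, using the closed-form variance of
  the linear predictor under the generator.
* Waist circumference from a power law with exponents −5/6 and 2/3 — the
  values that make the ABSI analogue exactly independent of height and BMI
  — with female offset −0.06 and log-noise sd 0.055.
* Mortality from a Gompertz baseline (a = 3·10⁻⁵/yr, b = 0.09/yr, an
  arbitrary but standard adult-mortality calibration, yielding a ~27% event
  fraction over 20 years) times exp of additive component functions of the
  four index z scores: U-shaped in BMI (curvature 0.12, minimum at
  z = −0.5) and HI (curvature 0.08, minimum 0), linear in ABSI (slope 0.15,
  close to published per-SD hazard ratios) and height (slope −0.05); plus
  sex (−0.4) and race (+0.2) terms.  Death ages are drawn by
  inverse-transform from the conditional Gompertz survival function, with
  administrative censoring 20 years after entry and no loss to follow-up.
* The hazard layer's z scores are computed against the generated cohort's
  own reference statistics, so the "true" component functions live in the
  same units the analysis estimates.

What the generator does **not** emulate: survey cluster/oversampling
design, measurement error, secular trends, loss to follow-up, or
dependence of body size on age.  Passing recovery tests on these cohorts
demonstrates correctness of the estimation machinery under the model's own
assumptions — not that real cohorts satisfy those assumptions.

## Problem sizes used in the test suite

Recovery checks run at n = 20,000 (the scale at which coefficient SEs are
small enough for 3-SE bounds to be meaningful); structural and invariance
checks use 2,000–6,000; the ARI-superiority and transfer checks use 20 and
10 seeded replicates at n = 20,000.  The brute-force oracles for the
partial likelihood and concordance run on hundreds of random instances of
up to 6 subjects, where exhaustive enumeration is feasible.

## Known limitations

* No time-varying covariates, stratified baselines, competing risks or
  frailties; no survey-design variance.
* The explained-variation formula is one convention among several; absolute
  R² values should not be compared across software without checking the
  formula.
* Reference tables use step-function (binned) normals; no growth-chart
  style smoothing.
* ARI assumes additivity of the four log hazards; interactions between
  indices are not modeled.
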