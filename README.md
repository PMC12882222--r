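# phasorckm

Circadian disruption — the decoupling of daily behaviour from the
light–dark cycle — is an emerging risk factor for the cardio-kidney-metabolic
(CKM) syndrome, the progressive entanglement of obesity, diabetes, chronic
kidney disease and cardiovascular disease. phasorckm is an R package for
epidemiologists working with wearable-device cohorts: it measures
light–activity alignment from minute-level actigraphy, stages participants
on the CKM 0–4 continuum, and estimates survey-weighted associations between
poor alignment and advanced CKM or mortality.

## What it computes

**Phasor analysis.** For each participant, lux is saturated at 10,000 and
log-transformed (`log10(min(lux, 10⁴) + 1)`), activity counts likewise
(no ceiling), each 24-h day standardized, and the circular cross-correlation

&nbsp;&nbsp;&nbsp;&nbsp;*r*(τ) = (1/N) Σₜ *x*(t) · *y*((t+τ) mod N),  N = 1440

averaged across days. Its 24-hour Fourier component
*P* = (2/N) Σ*r*(τ)e^(−2πiτ/N) gives the **phasor magnitude** |*P*|
(strength/regularity of light–activity coupling; 1 for a phase-locked
sinusoid pair, bounded by 4/π) and the **acrophase** −arg(*P*)·12/π hours in
(−12, 12], positive when activity lags light (evening preference).

**CKM staging.** Deterministic rules: stage 4 = CVD history; stage 3 =
very-high-risk CKD (KDIGO heat map from CKD-EPI 2021 eGFR × albuminuria) or
an elevated 10-year CVD-risk flag; stage 2 = triglycerides ≥ 135 mg/dL,
hypertension, diabetes, metabolic syndrome, or moderate/high-risk CKD;
stage 1 = BMI ≥ 25, central adiposity, or prediabetes; advanced = stages 3–4.

**Design-based models.** Weighted logistic (advanced CKM) and weighted Cox
(all-cause, cardiovascular, premature mortality) regressions on weighted
magnitude quartiles (reference Q4) under four nested adjustment models, with
Taylor-linearized stratum/PSU variance, restricted-cubic-spline
dose–response curves, age/sex-stratified refits, and predicted survival
curves — all implemented in-package and validated against classical fits in
degenerate designs.

**Synthetic data.** `simulate_actigraphy()` (known coupling ρ and lag) and
`simulate_cohort()` (known OR/HR effects, stratified two-PSU design) give
every downstream stage a ground truth, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(phasorckm)
library(dplyr)

# one participant: 7 days, strong coupling, activity 1.5 h after light
rec <- simulate_actigraphy(n_days = 7, coupling_rho = 0.8,
                           lag_hours = 1.5, seed = 42)
compute_phasor(segment_days(rec))
#> <phasor_result> magnitude 0.837, acrophase +1.49 h, 7 days

# a survey cohort with known effects, staged and modelled
co <- simulate_cohort(n = 2000, seed = 42)     # truth: OR 1.8, HR 2.0 on Q1
staged <- ckm_stage(co)
count(staged, ckm_stage)
#>   ckm_stage     n
#> 1         1   256
#> 2         2  1384
#> 3         3    38
#> 4         4   322

fit_quartile_models(staged, outcome = "advanced", models = c(1, 4)) |>
  filter(term == "Q1")
#>   outcome  model term  estimate conf.low conf.high std.error  p.value     n events
#> 1 advanced     1 Q1        2.12     1.47      3.08     0.181  2.48e-4  2000    360
#> 2 advanced     4 Q1        2.19     1.52      3.15     0.178  1.26e-4  2000    360
```

The magnitude 0.837 reflects the 0.8 coupling (1.0 would be a noise-free
phase-locked sinusoid); the acrophase recovers the injected +1.5 h lag to
the minute grid. In the cohort, participants in the worst-aligned quartile
(Q1) show about twice the odds of advanced CKM relative to Q4 — the
injected odds ratio of 1.8 sits inside both confidence intervals.

`run_pipeline(pipeline_config(...))` chains everything — preprocessing, QC,
phasors, staging, exclusion accounting, all four outcome models, spline and
survival curves — into one seeded, byte-reproducible run that writes tidy
CSVs and a manifest. `autoplot()` methods cover the result types
(forest tables, spline curves, survival curves), and `tidy()`/`glance()`
work on every fit.

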