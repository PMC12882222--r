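---
title: "Methods: phasor analysis of light-activity coupling and design-based CKM risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasor analysis of light-activity coupling and design-based CKM risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phasorckm quantifies how tightly a person's daily physical-activity rhythm is
coupled to their ambient light exposure, stages cardio-kidney-metabolic (CKM)
syndrome from clinical data, and estimates survey-weighted associations
between poor light-activity coupling and advanced CKM or mortality. This
vignette is the package's own account of the methods: the model, the knobs
that matter, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

## The phasor model

The raw inputs are minute-resolution lux and activity-count series from a
wrist-worn device. Ambient illuminance spans five orders of magnitude and the
circadian system's response saturates in daylight, so lux is ceilinged at
10,000 and log-transformed, `log10(min(lux, 10000) + 1)`; activity counts are
transformed the same way without a ceiling. Each 24-hour day (aligned to
midnight on the device grid) is then standardized to zero mean and unit
variance. Standardization makes the analysis invariant to the log base — a
base change is an affine map — so base 10 is a cosmetic choice, and it makes
the circular cross-correlation

$$ r(\tau) = \frac{1}{N}\sum_{t=0}^{N-1} x(t)\, y\big((t+\tau) \bmod N\big), \qquad N = 1440, $$

a true correlation, bounded by 1 in absolute value. `circular_xcorr()`
evaluates this with the FFT; the test suite pins the FFT path to the naive
O(N²) loop at 10⁻¹⁰, so the fast path never silently drifts from the
definition.

Per-day correlation functions are averaged across the recording and the
24-hour Fourier component extracted:

$$ P = \frac{2}{N} \sum_{\tau=0}^{N-1} \bar r(\tau)\, e^{-2\pi i \tau / N}. $$

The **phasor magnitude** is |P| and the **acrophase** is −arg(P) · 12/π
hours, wrapped into (−12, 12]. Three conventions deserve comment:

* **Scale.** The 2/N scaling makes a perfectly phase-locked sinusoid pair
  score exactly 1, and |r| ≤ 1 bounds the magnitude by 4/π ≈ 1.27 (attained
  by a square-wave correlation). Published applications of light-activity
  phasors do not pin down their normalization; fixing "sinusoid = 1" makes
  the scale auditable, and both the unit score and the bound are tested.
* **Sign.** Activity *lagging* light yields a positive acrophase (evening
  preference). Rather than trusting the algebra, a lag-equivariance property
  test shifts activity by +k minutes and checks the acrophase moves by
  +k/60 hours.
* **Aggregation.** The Fourier extraction is linear in r, so averaging
  per-day correlation functions is identical to averaging per-day phasors
  (tested to 10⁻¹²). A `method = "concatenated"` switch computes one
  correlation function over the whole record instead; for stationary
  recordings the two agree, and the per-day average is the default because
  it is robust to day-to-day amplitude drift.

Day-level quality control: a day with under 80% valid minutes is dropped,
surviving invalid minutes are linearly interpolated *within the day* before
the transforms (zero-filling would inject spurious 24-h power), a day with
zero variance in either transformed signal (constant darkness) is rejected,
and a participant needs 4 surviving days. The 0.8 / 4 thresholds are
explicit configuration, not claims about any particular study's QC.

## CKM staging

`ckm_stage()` is a deterministic rule engine. The assigned stage is the
maximum over all satisfied rules: stage 4 for clinical CVD history; stage 3
for very-high-risk CKD on the KDIGO heat map or an elevated 10-year CVD risk
flag; stage 2 for triglycerides ≥ 135 mg/dL, hypertension, diabetes,
metabolic syndrome (harmonized ATP-III, ≥ 3 of 5 components, inclusive
thresholds), or moderate/high-risk CKD; stage 1 for BMI ≥ 25 kg/m²,
waist ≥ 88/102 cm (female/male), or prediabetes (fasting glucose
100–124 mg/dL, HbA1c 5.7–6.4%, or antidiabetic therapy); stage 0 otherwise.
Advanced CKM is stages 3–4.

Choices worth flagging:

* The prediabetes glucose band is implemented as printed in the staging
  criteria this package follows, 100–124 mg/dL — note the conventional band
  runs to 125. The difference affects only FPG values of exactly 125.
* Whether antidiabetic therapy belongs in the stage-1 prediabetes rule is
  genuinely ambiguous (it also marks treated diabetes, a stage-2 condition);
  it is included by default and switchable
  (`antidiabetic_rx_is_prediabetes = FALSE`).
* The 10-year CVD risk equation behind stage 3 is deliberately pluggable: a
  precomputed boolean column (`ten_year_cvd_risk_elevated`). No specific
  risk equation is bundled; absent the column, the rule simply never fires.
* eGFR uses the race-free CKD-EPI 2021 creatinine equation; KDIGO G/A
  boundaries are inclusive as published (eGFR 90 is G1, UACR 30 and 300 are
  both A2), and all 18 heat-map cells are asserted in the tests.
* Missing data: a rule with missing inputs is "not fired". A profile where
  no rule fires and *no* stage 1–4 rule was evaluable is unstageable (`NA`)
  and excluded downstream. This is the most conservative policy that never
  stages a person on absent evidence yet never discards a person with any
  decisive measurement; a monotone-dominance property test (adding a risk
  factor can never lower the stage) guards the rule interactions.

## Design-based estimation

The analysis table carries sampling weights, strata, and PSUs
(two-per-stratum, the masked-variance-unit layout of public-use national
surveys). The `survey` design machinery is implemented in-package:

* **Logistic** (`weighted_logistic()`): weighted maximum pseudo-likelihood
  via `glm`, variance by Taylor linearization — score contributions
  premultiplied by the inverse information, summed to PSU totals, combined
  with the stratified between-PSU with-replacement estimator
  Σₕ nₕ/(nₕ−1) Σ_c (e_hc − ē_h)(e_hc − ē_h)ᵀ.
* **Cox** (`weighted_cox()`): weighted partial likelihood via
  `survival::coxph` with Efron tie handling (follow-up is in months, so ties
  are common and Efron is the lower-bias choice), variance from weighted
  dfbeta residuals aggregated the same way. CVD mortality is a
  cause-specific hazard: non-CVD deaths are censored. Premature mortality
  (`premature_death_model()`) defines the event as death before attained age
  70, censors follow-up at the month a participant turns 70, and excludes
  those 70+ at baseline; redefining the event without the age-70
  administrative censoring would be an alternative reading, and the censored
  version is the one implemented because it keeps the risk set honest.
* **Confidence intervals** use a t reference with design degrees of freedom
  (#PSUs − #strata), the standard convention for these designs. With 15
  strata × 2 PSUs this matters: a normal reference would undercover by
  roughly two points.
* In the degenerate design — equal weights, every observation its own PSU,
  one stratum — both estimators provably collapse to their classical
  counterparts, and the tests assert equality to 10⁻⁶ (coefficients) with
  the variance matching the HC0 sandwich up to n/(n−1).
* Lone PSUs in a stratum are an error by default (naming the stratum);
  subgroup analyses use `single_psu = "adjust"` (grand-mean centering),
  since stratified refits routinely orphan PSUs.

Exposure is phasor magnitude in weighted quartiles, Q4 (best-coupled) the
reference. Sequential adjustment: Model 1 unadjusted; Model 2 + age, sex,
race, education, household income; Model 3 + smoking and weekly alcohol;
Model 4 + hypertension and diabetes. Nonlinearity is probed with restricted
cubic splines in the Harrell parameterisation — 4 knots at the 5/35/65/95
weighted percentiles by default, nonlinear columns exactly zero below the
first knot, linear beyond the boundary knots (checked by finite
differences) — with curves normalized to 1 at the weighted median and
delta-method bands. Predicted survival curves use the weighted Breslow
baseline with covariates at weighted means (weighted modal level for
factors), truncated at the last event time.

## What the synthetic generator emulates

`simulate_actigraphy()` builds, on the transformed scale, activity as
ρ · (standardized light template shifted by the lag) + (1−ρ) · white noise,
then inverts the log transforms so the files it writes are raw lux/counts.
ρ is the ground-truth coupling and the lag the ground-truth acrophase
(realised at one-minute resolution). The default template is a truncated
cosine: zero overnight, 1000 lux peak at 13:00 — chosen to exercise the
log transform's dynamic range; pass a template peaking above 10,000 lux to
exercise saturation. Nonwear is injected as contiguous 1–4 hour blocks,
mimicking device removal and stressing the valid-day rule, not scattered
minutes. Defaults (7 days, noise SD 0.3/1.0 on the transformed scale) give
magnitudes spanning roughly 0.05–0.9 as ρ runs 0→1, with the median
magnitude strictly increasing in ρ (tested over 50 seeds per ρ).

`simulate_cohort()` draws magnitude from a truncated normal (mean 0.34, SD
0.11 — the scale typical of community cohorts), cuts weighted quartiles, and
injects effects *only* on the Q1 indicator: log-odds `beta_advanced`
(default log 1.8) for advanced CKM, log-hazards `log_hr_allcause` /
`log_hr_cvd` (default log 2) on two competing exponential cause-specific
hazards (30% of the baseline 0.003/month hazard is cardiovascular),
exponential censoring at 0.002/month with administrative censoring at 120
months. Weights are log-uniform on [1, 10], independent of everything, over
15 strata × 2 PSUs. Two deliberate simplifications keep the estimand clean:
covariates are distributional realism only (no outcome effects, so the Q1
coefficient is the estimand under every adjustment model, sidestepping
logistic non-collapsibility), and clinical staging fields are generated
*conditionally on* the drawn advanced indicator (advanced rows receive CVD
history or very-high-risk CKD via an inverted CKD-EPI equation), so staging
the synthetic cohort reproduces the indicator exactly.

What passing these tests shows: the estimators recover injected effects with
93–97% CI coverage (500 replicates at n = 2000), the phasor machinery is
exact on analytic cases, and the pipeline is deterministic. What it does not
show: real actigraphy has autocorrelated, non-Gaussian noise, weekday
structure, and nonwear correlated with behaviour; real surveys have
informative weights and within-PSU correlation; real confounding is not
switched off. Results on synthetic data validate the machinery, not any
epidemiological claim.

## Problem sizes and numerics

The shipped tests and the acceptance script use cohorts of 200–5000, 4–9 day
recordings, and 100–500 replicate simulations — sizes chosen so the whole
suite exercises every claim in a few minutes on one core while keeping
Monte-Carlo error well inside the asserted bands. Numerical tie-breaks worth
recording: weighted quantiles use the left-continuous inverse CDF (so
quartile cutpoints are data values and ties go to the lower quartile);
standardization uses the population (1/N) variance so r(0) = 1 exactly;
acrophase wrapping maps −12 h to +12 h; zero-variance days are rejected
rather than producing NaN correlations; separation in the logistic fit is
flagged (infinite CIs) rather than fatal, and Cox levels with no events are
reported non-estimable.

## Limitations

The correlation-function phasor is the only circadian metric implemented (no
IS/IV, M10/L5, or cosinor of the raw signals); competing-risks models beyond
cause-specific hazards, multiple imputation, and descriptive hypothesis
tests are out of scope; and the pipeline's exclusion flow mirrors a typical
enrolment flowchart (age, stageability, anthropometrics, survival linkage,
device data) but any real analysis should re-examine that order against its
own data provenance.
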