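# Synthetic survey cohort with known ground truth: exposure quartiles,
# covariates, clinical staging fields consistent with the generated
# advanced-CKM indicator, survival outcomes, and a stratified two-PSU design.

# Invert the CKD-EPI 2021 equation: creatinine giving a target eGFR.
scr_for_egfr <- function(egfr, age, sex) {
  vapply(seq_along(egfr), function(i) {
    stats::uniroot(
      function(s) egfr_ckd_epi_2021(s, age[i], sex[i]) - egfr[i],
      interval = c(0.05, 40), tol = 1e-8
    )$root
  }, numeric(1))
}

# Draw a (G, A) KDIGO cell, optionally restricted to / away from very-high
# risk, with marginals resembling a community overweight/obese cohort.
draw_kidney <- function(n, very_high) {
  g_levels <- c("G1", "G2", "G3a", "G3b", "G4", "G5")
  a_levels <- c("A1", "A2", "A3")
  g_prob <- c(0.591, 0.330, 0.050, 0.022, 0.005, 0.002)
  a_prob <- c(0.878, 0.102, 0.020)
  cells <- expand.grid(g = g_levels, a = a_levels, stringsAsFactors = FALSE)
  cells$p <- g_prob[match(cells$g, g_levels)] * a_prob[match(cells$a, a_levels)]
  vh <- as.character(kdigo_risk(cells$g, cells$a)) == "very_high"
  keep <- if (very_high) vh else !vh
  cells <- cells[keep, , drop = FALSE]
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = cells$p)
  cells[idx, c("g", "a")]
}

egfr_band <- function(g) {
  lo <- c(G1 = 90, G2 = 60, G3a = 45, G3b = 30, G4 = 15, G5 = 5)[g]
  hi <- c(G1 = 115, G2 = 89.9, G3a = 59.9, G3b = 44.9, G4 = 29.9, G5 = 14.9)[g]
  runif(length(g), lo, hi)
}

uacr_band <- function(a) {
  exp(runif(length(a),
            log(c(A1 = 3, A2 = 30, A3 = 301)[a]),
            log(c(A1 = 29.9, A2 = 300, A3 = 3000)[a])))
}

#' Simulate a survey cohort with known ground truth
#'
#' Generates an analysis table emulating a two-cycle national survey of
#' overweight/obese adults: a phasor-magnitude exposure (or a supplied one),
#' weighted quartiles, demographic and lifestyle covariates, clinical fields
#' spanning all five CKM stages, an advanced-CKM indicator drawn from a
#' logistic model with log-odds `beta_advanced` on the Q1 (worst-aligned)
#' indicator, survival from exponential cause-specific proportional hazards
#' with log-hazard effects `log_hr_allcause` / `log_hr_cvd` on Q1,
#' independent exponential censoring with administrative censoring at
#' `admin_censor_months`, and a stratified design with `psus_per_stratum`
#' PSUs per stratum and log-uniform weights.
#'
#' Clinical staging fields are drawn *conditionally on* the generated
#' advanced indicator (advanced rows receive CVD history or very-high-risk
#' CKD; non-advanced rows are kept below stage 3), so [ckm_stage()] on the
#' output reproduces the latent indicator exactly; covariates carry no
#' outcome effects of their own, keeping the injected Q1 coefficients the
#' estimand under every adjustment model. Ground truth is attached as the
#' `truth` attribute.
#'
#' All-cause mortality is the sum of the two cause-specific hazards, so the
#' all-cause Q1 log-hazard equals `log_hr_allcause` exactly when
#' `log_hr_cvd == log_hr_allcause` (the default).
#'
#' @param n Number of participants (>= 4 per PSU).
#' @param beta_advanced Log-odds of advanced CKM for Q1 vs Q4.
#' @param log_hr_allcause,log_hr_cvd Q1-vs-Q4 log hazard ratios for the
#'   non-CVD and CVD cause-specific hazards.
#' @param baseline_hazard Baseline all-cause hazard per month.
#' @param cvd_fraction Fraction of the baseline hazard attributed to
#'   cardiovascular causes.
#' @param censor_rate Exponential censoring rate per month.
#' @param admin_censor_months Administrative censoring horizon (months).
#' @param n_strata,psus_per_stratum Design sizes (every stratum gets
#'   `psus_per_stratum` PSUs).
#' @param weight_range Length-2 range for the log-uniform sampling weights.
#' @param magnitude Optional per-participant phasor magnitudes (length `n`,
#'   `NA` allowed); when `NULL`, drawn from a truncated normal centred at
#'   0.34 (sd 0.11).
#' @param clinical Generate the clinical staging fields? Setting `FALSE`
#'   skips the (comparatively slow) creatinine inversion when only the
#'   outcome/design columns are needed, e.g. in replicate simulations.
#' @param seed Integer seed.
#' @return A tibble with one row per participant; ground-truth parameters in
#'   `attr(, "truth")`.
#' @export
simulate_cohort <- function(n = 2000,
                            beta_advanced = log(1.8),
                            log_hr_allcause = log(2.0),
                            log_hr_cvd = log(2.0),
                            baseline_hazard = 0.003,
                            cvd_fraction = 0.3,
                            censor_rate = 0.002,
                            admin_censor_months = 120,
                            n_strata = 15,
                            psus_per_stratum = 2,
                            weight_range = c(1, 10),
                            magnitude = NULL,
                            clinical = TRUE,
                            seed = 1L) {
  stopifnot(
    n >= 4 * n_strata * psus_per_stratum,
    baseline_hazard > 0, censor_rate > 0,
    all(weight_range > 0), length(weight_range) == 2,
    psus_per_stratum >= 2
  )
  set.seed(as.integer(seed))

  if (is.null(magnitude)) {
    magnitude <- pmin(pmax(rnorm(n, 0.34, 0.11), 0.02), 4 / pi - 0.01)
  }
  stopifnot(length(magnitude) == n)

  stratum <- sprintf("S%02d", rep_len(seq_len(n_strata), n))
  psu <- paste0(stratum, "-P", rep_len(seq_len(psus_per_stratum),
                                       ceiling(n / psus_per_stratum))[seq_len(n)])
  # shuffle so PSU membership is independent of everything else
  ord <- sample.int(n)
  stratum <- stratum[ord]
  psu <- psu[ord]
  weight <- exp(runif(n, log(weight_range[1]), log(weight_range[2])))

  q <- rep(factor(NA, levels = paste0("Q", 1:4)), n)
  has_mag <- is.finite(magnitude)
  if (sum(has_mag) >= 4) {
    qa <- assign_quartiles(magnitude[has_mag], weight[has_mag])
    q[has_mag] <- qa$labels
  }
  q1 <- fired(q == "Q1")

  age <- pmin(pmax(rnorm(n, 52, 16.5), 20), 84)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.507, 0.493))
  race <- sample(c("mexican_american", "hispanic", "nh_white", "nh_black", "other"),
                 n, replace = TRUE, prob = c(0.136, 0.102, 0.418, 0.25, 0.094))
  education <- sample(c("less_than_hs", "hs_grad", "some_college", "college_grad"),
                      n, replace = TRUE, prob = c(0.231, 0.23, 0.315, 0.224))
  income <- sample(c("<20k", "20-45k", "45-75k", "75k+"),
                   n, replace = TRUE, prob = c(0.229, 0.344, 0.178, 0.249))
  smoking <- sample(c("no", "yes"), n, replace = TRUE, prob = c(0.825, 0.175))
  alcohol <- sample(c("none", "<1/week", "1/week-1/day", ">=1/day"),
                    n, replace = TRUE, prob = c(0.383, 0.353, 0.228, 0.036))
  hypertension <- runif(n) < 0.503
  diabetes <- runif(n) < 0.228

  # Advanced CKM from the logistic model; intercept set so the marginal
  # prevalence sits near one in five, as in community overweight/obese adults.
  eta <- qlogis(0.17) + beta_advanced * q1
  advanced <- runif(n) < plogis(eta)

  # Clinical fields consistent with the indicator (BMI >= 25 throughout:
  # this is an overweight/obese cohort).
  bmi <- pmax(rnorm(n, 32.1, 6.3), 25)
  waist <- pmax(rnorm(n, ifelse(sex == "female", 98, 108), 12), 70)
  tg <- exp(rnorm(n, log(120), 0.45))
  hdl <- pmax(rnorm(n, ifelse(sex == "female", 55, 47), 12), 20)
  sbp <- pmax(rnorm(n, ifelse(hypertension, 138, 120), 12), 90)
  dbp <- pmax(rnorm(n, ifelse(hypertension, 84, 72), 8), 50)
  fpg <- exp(rnorm(n, log(ifelse(diabetes, 150, 97)), 0.12))
  hba1c <- pmax(rnorm(n, ifelse(diabetes, 7.2, 5.5), 0.4), 4.2)
  on_antidiabetic_rx <- diabetes & runif(n) < 0.7
  on_antihypertensive_rx <- hypertension & runif(n) < 0.75

  # Kidney fields: non-advanced rows stay out of very-high KDIGO risk,
  # advanced rows without CVD history are forced into it.
  cvd_history <- rep(FALSE, n)
  cvd_history[advanced] <- runif(sum(advanced)) < 0.9
  via_ckd <- advanced & !cvd_history
  if (clinical) {
    kid <- draw_kidney(n, very_high = FALSE)
    if (any(via_ckd)) kid[via_ckd, ] <- draw_kidney(sum(via_ckd), very_high = TRUE)
    egfr_target <- egfr_band(kid$g)
    scr <- scr_for_egfr(egfr_target, age, sex)
    uacr <- uacr_band(kid$a)
  } else {
    scr <- rep(NA_real_, n)
    uacr <- rep(NA_real_, n)
  }

  # Survival: competing exponential cause-specific hazards with Q1 effects.
  h_cvd <- baseline_hazard * cvd_fraction * exp(log_hr_cvd * q1)
  h_oth <- baseline_hazard * (1 - cvd_fraction) * exp(log_hr_allcause * q1)
  t_cvd <- rexp(n, h_cvd)
  t_oth <- rexp(n, h_oth)
  t_death <- pmin(t_cvd, t_oth)
  t_cens <- pmin(rexp(n, censor_rate), admin_censor_months)
  followup_months <- pmin(t_death, t_cens)
  dead <- t_death <= t_cens
  cvd_death <- dead & t_cvd <= t_oth
  age_at_exit <- age + followup_months / 12

  out <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    magnitude = magnitude,
    quartile = q,
    age, sex, race, education, income, smoking, alcohol,
    hypertension, diabetes,
    bmi, waist_cm = waist,
    triglycerides_mg_dl = tg, hdl_mg_dl = hdl,
    sbp, dbp, fpg_mg_dl = fpg, hba1c_pct = hba1c,
    on_antidiabetic_rx, on_antihypertensive_rx,
    scr_mg_dl = scr, uacr_mg_g = uacr,
    cvd_history,
    ten_year_cvd_risk_elevated = FALSE,
    advanced_ckm = advanced,
    followup_months, dead, cvd_death, age_at_exit,
    weight, stratum, psu
  )
  attr(out, "truth") <- list(
    beta_advanced = beta_advanced,
    log_hr_allcause = log_hr_allcause,
    log_hr_cvd = log_hr_cvd,
    baseline_hazard = baseline_hazard,
    cvd_fraction = cvd_fraction,
    censor_rate = censor_rate,
    quartile_cutpoints = if (sum(has_mag) >= 4) qa$cutpoints else NULL
  )
  out
}
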