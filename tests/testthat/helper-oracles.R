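# Independent oracles and fixture builders used across the suite.

# Brute-force O(N^2) circular cross-correlation (the reference the FFT path
# must match).
naive_xcorr <- function(x, y) {
  n <- length(x)
  vapply(0:(n - 1), function(tau) {
    sum(x * y[((seq_len(n) - 1 + tau) %% n) + 1]) / n
  }, numeric(1))
}

# Standardized sinusoidal day pairs with a known activity-after-light lag.
sinusoid_days <- function(n_days = 7, lag_minutes = 0, mpd = 1440,
                          phase_minutes = 780) {
  t <- 0:(mpd - 1)
  light <- cos(2 * pi * (t - phase_minutes) / mpd)
  act <- cos(2 * pi * (t - phase_minutes - lag_minutes) / mpd)
  std <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  tibble::tibble(
    day_index = seq_len(n_days),
    valid_fraction = 1,
    light_t = replicate(n_days, std(light), simplify = FALSE),
    activity_t = replicate(n_days, std(act), simplify = FALSE)
  )
}

random_standardized <- function(n) {
  x <- rnorm(n)
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

# Random clinical profiles for staging property tests. complete = TRUE gives
# fully observed profiles; otherwise fields go missing independently.
random_profiles <- function(n, complete = TRUE, miss = 0.15) {
  hole <- function(x) {
    if (complete) return(x)
    x[runif(length(x)) < miss] <- NA
    x
  }
  tibble::tibble(
    sex = sample(c("female", "male"), n, TRUE),
    age = runif(n, 20, 80),
    waist_cm = hole(runif(n, 60, 140)),
    bmi = hole(runif(n, 18, 45)),
    fpg_mg_dl = hole(runif(n, 70, 220)),
    hba1c_pct = hole(runif(n, 4.5, 10)),
    on_antidiabetic_rx = hole(runif(n) < 0.15),
    triglycerides_mg_dl = hole(exp(runif(n, log(40), log(500)))),
    hdl_mg_dl = hole(runif(n, 25, 90)),
    sbp = hole(runif(n, 95, 180)),
    dbp = hole(runif(n, 55, 110)),
    on_antihypertensive_rx = hole(runif(n) < 0.3),
    hypertension = hole(runif(n) < 0.4),
    diabetes = hole(runif(n) < 0.2),
    scr_mg_dl = hole(exp(runif(n, log(0.4), log(4)))),
    uacr_mg_g = hole(exp(runif(n, log(2), log(1500)))),
    cvd_history = hole(runif(n) < 0.1),
    ten_year_cvd_risk_elevated = hole(runif(n) < 0.08)
  )
}

# iid equal-weight single-PSU-per-observation "design" for degeneracy tests.
iid_design <- function(data) {
  data$weight <- 1
  data$stratum <- "all"
  data$psu <- seq_len(nrow(data))
  data
}
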