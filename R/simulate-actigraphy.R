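# Synthetic minute-level actigraphy with a known light-activity coupling.

#' Default daily light template
#'
#' A truncated-cosine daylight curve: zero overnight, rising after ~07:00 and
#' peaking at 1000 lux at 13:00. Exercises both the log transform and (via
#' `peak_lux` above 10,000) the lux saturation rule.
#'
#' @param minutes_per_day Minutes in a day (default 1440).
#' @param peak_lux Peak of the curve in lux.
#' @param peak_time_hours Clock time of the peak, hours after midnight.
#' @return Nonnegative numeric vector of length `minutes_per_day` (lux).
#' @export
default_light_profile <- function(minutes_per_day = 1440, peak_lux = 1000,
                                  peak_time_hours = 13) {
  t_hours <- (seq_len(minutes_per_day) - 1) / minutes_per_day * 24
  peak_lux * pmax(0, cos(2 * pi * (t_hours - peak_time_hours) / 24))
}

#' Simulate a minute-level light/activity recording
#'
#' Generates a minute grid of lux and activity counts in which, on the
#' log-transformed scale, activity equals `coupling_rho` times the
#' standardized (transformed) daily light template shifted by `lag_hours`,
#' plus `(1 - coupling_rho)` times white noise. `coupling_rho` is therefore
#' the ground-truth coupling strength the downstream phasor magnitude should
#' track, and `lag_hours` the ground-truth acrophase (positive = activity
#' lags light). Raw series are obtained by inverting the `log10(x + 1)`
#' transform, so a pipeline run on the output recovers the constructed
#' transformed-scale signals exactly (up to floating point).
#'
#' Nonwear is injected as contiguous invalid blocks (device-removal style)
#' rather than scattered minutes.
#'
#' @param n_days Number of recorded days.
#' @param minutes_per_day Minutes per day (>= 24; default 1440).
#' @param coupling_rho Coupling strength in `[0, 1]`.
#' @param lag_hours Activity-after-light lag in hours, wrapped into
#'   `(-12, 12]`; realised at one-minute resolution.
#' @param light_profile Daily light template of length `minutes_per_day`.
#'   Interpreted in lux when `profile_scale = "lux"`, or directly on the
#'   `log10(lux + 1)` scale when `profile_scale = "transformed"` (values must
#'   be nonnegative on either scale).
#' @param profile_scale `"lux"` or `"transformed"`.
#' @param noise_sd_light,noise_sd_activity Noise standard deviations on the
#'   transformed scale.
#' @param missing_fraction Fraction of minutes flagged invalid, in `[0, 1)`.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param participant_id Identifier carried into the output.
#' @return A tibble with columns `participant_id`, `minute` (0-based index,
#'   minute 0 = midnight), `lux`, `activity`, `valid`.
#' @export
#' @examples
#' rec <- simulate_actigraphy(n_days = 2, coupling_rho = 0.8, seed = 1)
#' dplyr::count(rec, valid)
simulate_actigraphy <- function(n_days = 7,
                                minutes_per_day = 1440,
                                coupling_rho = 0.5,
                                lag_hours = 0,
                                light_profile = default_light_profile(minutes_per_day),
                                profile_scale = c("lux", "transformed"),
                                noise_sd_light = 0.3,
                                noise_sd_activity = 1,
                                missing_fraction = 0,
                                seed = 1L,
                                participant_id = "P0001") {
  profile_scale <- match.arg(profile_scale)
  if (!is.numeric(coupling_rho) || length(coupling_rho) != 1L ||
      is.na(coupling_rho) || coupling_rho < 0 || coupling_rho > 1) {
    abort_ckm("coupling_rho must be a single value in [0, 1]", "ckm_domain_error")
  }
  if (!is.numeric(lag_hours) || length(lag_hours) != 1L || is.na(lag_hours) ||
      abs(lag_hours) > 24) {
    abort_ckm("lag_hours must be a single finite offset within a 24-hour span",
              "ckm_domain_error")
  }
  lag_hours <- wrap_half_day(lag_hours)
  stopifnot(
    n_days >= 1, minutes_per_day >= 24,
    length(light_profile) == minutes_per_day,
    noise_sd_light >= 0, noise_sd_activity >= 0,
    missing_fraction >= 0, missing_fraction < 1
  )
  if (any(light_profile < 0)) {
    abort_ckm("light_profile must be nonnegative everywhere", "ckm_domain_error")
  }

  set.seed(as.integer(seed))
  n <- n_days * minutes_per_day
  tod <- rep.int(seq_len(minutes_per_day), n_days)  # 1-based time of day

  # Template on the transformed (log10 lux + 1) scale, saturated at 10,000 lux.
  template_t <- if (profile_scale == "lux") {
    transform_light(light_profile)
  } else {
    light_profile
  }
  profilez <- standardize_pop(template_t)

  light_t <- template_t[tod] + if (noise_sd_light > 0) {
    rnorm(n, 0, noise_sd_light)
  } else 0

  lag_minutes <- as.integer(round(lag_hours * 60 * minutes_per_day / 1440))
  shifted_idx <- ((tod - 1 - lag_minutes) %% minutes_per_day) + 1
  activity_core <- profilez[shifted_idx]
  activity_t <- coupling_rho * activity_core +
    (1 - coupling_rho) * if (noise_sd_activity > 0) {
      rnorm(n, 0, noise_sd_activity)
    } else 0

  # Invert the transforms; an affine placement on the log scale keeps raw
  # activity positive and is invisible to the per-day standardization.
  lux <- pmax(10^pmax(light_t, 0) - 1, 0)
  activity <- pmax(10^(0.5 * activity_t + 2) - 1, 0)

  valid <- rep(TRUE, n)
  n_missing <- round(missing_fraction * n)
  while (n_missing > 0) {
    block <- min(sample(60:240, 1L), n_missing)
    start <- sample.int(n - block + 1L, 1L)
    idx <- start:(start + block - 1L)
    fresh <- sum(valid[idx])
    valid[idx] <- FALSE
    n_missing <- n_missing - fresh
  }
  lux[!valid] <- 0
  activity[!valid] <- 0

  tibble::tibble(
    participant_id = participant_id,
    minute = 0:(n - 1L),
    lux = lux,
    activity = activity,
    valid = valid
  )
}
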