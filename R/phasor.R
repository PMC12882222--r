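# Phasor analysis: circular cross-correlation, its 24-hour Fourier component,
# and the per-participant magnitude/acrophase summary.

#' Circular cross-correlation of two standardized signals
#'
#' Computes `r(tau) = (1/N) * sum_t x(t) * y((t + tau) mod N)` for all lags
#' `tau = 0, ..., N-1`, i.e. the correlation between `x` and `y` as `y` is
#' circularly shifted against it. Inputs must be standardized (zero mean, unit
#' population variance), which makes `|r(tau)| <= 1` by Cauchy-Schwarz and
#' `r(0) = 1` when `y = x`. Implemented via the FFT; unit tests pin it to the
#' naive O(N^2) loop at 1e-10.
#'
#' @param x,y Standardized numeric vectors of equal length.
#' @param check Validate standardization (tolerance 1e-6)?
#' @return Numeric vector `r` of length `N`, lag in minutes along the index
#'   (lag 0 first).
#' @export
circular_xcorr <- function(x, y, check = TRUE) {
  if (length(x) != length(y)) {
    abort_ckm("x and y must have equal length", "ckm_domain_error")
  }
  if (check && (!is_standardized(x) || !is_standardized(y))) {
    abort_ckm("inputs must be standardized to zero mean and unit variance",
              "ckm_domain_error")
  }
  n <- length(x)
  Re(fft(Conj(fft(x)) * fft(y), inverse = TRUE)) / n^2
}

#' 24-hour Fourier component of a correlation function
#'
#' Extracts the fundamental (one cycle per day) component
#' `P = (2/N) * sum_tau r(tau) * exp(-1i * 2 * pi * tau / N)` of a length-`N`
#' daily correlation function. The 2/N scaling makes a perfectly phase-locked
#' sinusoid pair score `|P| = 1`; since `|r| <= 1`, `|P| <= 4/pi` always (the
#' square-wave extremal case).
#'
#' @param r Correlation function over one day (length = minutes per day).
#' @return A complex scalar.
#' @export
fundamental_component <- function(r) {
  n <- length(r)
  2 * fft(r)[[2L]] / n
}

#' Phasor magnitude and acrophase for one participant
#'
#' Averages the per-day circular cross-correlation functions between
#' standardized light and activity (or computes one correlation function over
#' the concatenated record), extracts the 24-hour component `P`, and reports
#' `magnitude = |P|` (strength/regularity of light-activity coupling) and
#' `acrophase_hours = -Arg(P) * 12 / pi` wrapped into `(-12, 12]`. The sign
#' convention makes activity lagging light positive ("evening preference");
#' it is verified by a lag-equivariance property test rather than assumed.
#' Because the Fourier extraction is linear in `r`, the day-averaged phasor
#' equals the mean of per-day phasors.
#'
#' @param days Day tibble from [segment_days()] (list-columns `light_t`,
#'   `activity_t`).
#' @param min_days Minimum days required; fewer yields an excluded result
#'   (`magnitude` `NA`), not an error.
#' @param method `"average_days"` (default) averages per-day correlation
#'   functions; `"concatenated"` computes one circular correlation over the
#'   concatenated multi-day record and reads off the one-cycle-per-day
#'   harmonic.
#' @param per_day Keep per-day phasors in the result?
#' @return An object of class `phasor_result`: a list with `magnitude`,
#'   `acrophase_hours`, `phasor`, `n_days_used`, `per_day_phasors`,
#'   `excluded`, `reason`. Use [tidy()] for a one-row tibble.
#' @export
compute_phasor <- function(days, min_days = 4,
                           method = c("average_days", "concatenated"),
                           per_day = FALSE) {
  method <- match.arg(method)
  n_days <- nrow(days)
  if (is.null(n_days) || n_days < min_days || n_days == 0L) {
    return(structure(
      list(magnitude = NA_real_, acrophase_hours = NA_real_,
           phasor = NA_complex_, n_days_used = n_days %||% 0L,
           per_day_phasors = NULL, excluded = TRUE,
           reason = sprintf("fewer than %d QC-passed days (%d)",
                            min_days, n_days %||% 0L)),
      class = "phasor_result"
    ))
  }

  if (method == "average_days") {
    rs <- purrr::map2(days$light_t, days$activity_t,
                      ~ circular_xcorr(.x, .y, check = FALSE))
    r_bar <- Reduce(`+`, rs) / n_days
    P <- fundamental_component(r_bar)
    pdp <- if (per_day) vapply(rs, fundamental_component, complex(1)) else NULL
  } else {
    x <- unlist(days$light_t)
    y <- unlist(days$activity_t)
    r_full <- circular_xcorr(x, y, check = FALSE)
    # one cycle per day = harmonic n_days of the concatenated record
    P <- 2 * fft(r_full)[[n_days + 1L]] / length(r_full)
    pdp <- NULL
  }

  structure(
    list(
      magnitude = Mod(P),
      acrophase_hours = wrap_half_day(-Arg(P) * 12 / pi),
      phasor = P,
      n_days_used = n_days,
      per_day_phasors = pdp,
      excluded = FALSE,
      reason = NA_character_
    ),
    class = "phasor_result"
  )
}

#' @export
print.phasor_result <- function(x, ...) {
  if (x$excluded) {
    cat("<phasor_result> excluded:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<phasor_result> magnitude %.3f, acrophase %+.2f h, %d days\n",
      x$magnitude, x$acrophase_hours, x$n_days_used
    ))
  }
  invisible(x)
}

#' @export
tidy.phasor_result <- function(x, ...) {
  tibble::tibble(
    magnitude = x$magnitude,
    acrophase_hours = x$acrophase_hours,
    n_days_used = x$n_days_used,
    excluded = x$excluded,
    reason = x$reason
  )
}

#' Phasor summary straight from a recording
#'
#' Convenience wrapper: segment + QC + phasor, returning a one-row tibble
#' suitable for row-binding across participants.
#'
#' @inheritParams segment_days
#' @inheritParams compute_phasor
#' @return One-row tibble: `participant_id`, `magnitude`, `acrophase_hours`,
#'   `n_days_used`, `excluded`, `reason`.
#' @export
phasor_from_recording <- function(rec, minutes_per_day = 1440,
                                  min_valid_fraction = 0.8, min_days = 4,
                                  method = "average_days") {
  days <- segment_days(rec, minutes_per_day, min_valid_fraction)
  res <- compute_phasor(days, min_days = min_days, method = method)
  dplyr::bind_cols(
    tibble::tibble(participant_id = as.character(rec$participant_id[1] %||% NA)),
    tidy(res)
  )
}

#' Quartile grouping with optional survey weights
#'
#' Cuts values at their (weighted) 25th/50th/75th percentiles. Q1 is the
#' lowest-magnitude group; a value tied with a cutpoint goes to the lower
#' quartile.
#'
#' @param values Numeric vector (at least 4 finite, distinct values).
#' @param weights Optional positive survey weights.
#' @return A list with `labels` (factor `Q1`-`Q4`, `NA` preserved) and
#'   `cutpoints` (the three cut values).
#' @export
#' @examples
#' assign_quartiles(1:8)$labels
assign_quartiles <- function(values, weights = NULL) {
  finite <- is.finite(values)
  if (sum(finite) < 4L || length(unique(values[finite])) < 4L) {
    abort_ckm("need at least 4 finite, distinct values to form quartiles",
              "ckm_degenerate_grouping")
  }
  w <- if (is.null(weights)) NULL else weights[finite]
  cut3 <- weighted_quantile(values[finite], c(0.25, 0.5, 0.75), w)
  if (any(duplicated(cut3))) {
    abort_ckm("quartile cutpoints are not distinct (degenerate grouping)",
              "ckm_degenerate_grouping")
  }
  lab <- 1L + (values > cut3[1]) + (values > cut3[2]) + (values > cut3[3])
  list(
    labels = factor(paste0("Q", lab), levels = paste0("Q", 1:4)),
    cutpoints = cut3
  )
}
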