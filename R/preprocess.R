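# Reading minute-level recordings and preparing QC-passed 24-hour day pairs.

#' Light and activity transforms
#'
#' Ambient light is saturated at 10,000 lux (the circadian response is
#' nonlinear and effectively ceilinged by daylight) and log-transformed:
#' `log10(min(lux, 10000) + 1)`. Activity counts are log-transformed the same
#' way without a saturation ceiling: `log10(counts + 1)`. Base 10 with the +1
#' offset keeps zeros finite; because every day is standardized afterwards,
#' the phasor magnitude and acrophase are invariant to the log base (a base
#' change is affine on the log scale).
#'
#' @param lux,counts Nonnegative numeric vectors. `NA` passes through.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' transform_light(c(0, 10000, 50000))
#' transform_activity(c(0, 9, 999))
transform_light <- function(lux) {
  if (any(lux < 0, na.rm = TRUE)) {
    abort_ckm("lux must be nonnegative", "ckm_domain_error")
  }
  log10(pmin(lux, 10000) + 1)
}

#' @rdname transform_light
#' @export
transform_activity <- function(counts) {
  if (any(counts < 0, na.rm = TRUE)) {
    abort_ckm("activity counts must be nonnegative", "ckm_domain_error")
  }
  log10(counts + 1)
}

#' Read a minute-level light/activity recording
#'
#' Supports a minute-level CSV dialect (columns: participant id, time as a
#' 0-based minute index or ISO-8601 timestamp, lux, activity, optional wear
#' flag) and the SAS-transport (XPT) minute-file dialect via the same column
#' mapping. Out-of-range or non-numeric minutes are flagged invalid rather
#' than dropped, so the minute grid is preserved; a missing declared column is
#' a configuration error and a non-constant time step a format error.
#'
#' @param path Path to the file.
#' @param dialect `"csv-minute"` or `"xpt-minute"`.
#' @param columns Named list mapping roles to column names; defaults are
#'   `list(id = "participant_id", time = "minute", lux = "lux",
#'   activity = "activity", valid = "valid")`. The `valid` column is optional
#'   in the file (all minutes assumed worn when absent).
#' @return A tibble with columns `participant_id`, `minute` (0-based, minute 0
#'   = midnight), `lux`, `activity`, `valid`, carrying the attribute
#'   `start_minute_of_day` used to align day boundaries.
#' @export
load_minute_records <- function(path,
                                dialect = c("csv-minute", "xpt-minute"),
                                columns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_ckm(paste0("actigraphy file not found: ", path), "ckm_config_error")
  }
  cols <- utils::modifyList(
    list(id = "participant_id", time = "minute", lux = "lux",
         activity = "activity", valid = "valid"),
    as.list(columns %||% list())
  )
  raw <- switch(dialect,
    "csv-minute" = readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    ),
    "xpt-minute" = {
      if (!requireNamespace("foreign", quietly = TRUE)) {
        abort_ckm("reading XPT files requires the 'foreign' package",
                  "ckm_config_error")
      }
      tibble::as_tibble(foreign::read.xport(path))
    }
  )
  names(raw) <- tolower(names(raw))
  cols <- lapply(cols, tolower)
  for (role in c("id", "time", "lux", "activity")) {
    if (!cols[[role]] %in% names(raw)) {
      abort_ckm(
        paste0("declared ", role, " column '", cols[[role]],
               "' not present in ", path),
        "ckm_config_error"
      )
    }
  }

  time_raw <- raw[[cols$time]]
  start_minute_of_day <- 0L
  if (all(grepl("^\\s*-?[0-9]+\\s*$", time_raw))) {
    minute <- as.integer(time_raw)
    if (any(diff(minute) != 1L)) {
      abort_ckm("time column is not a strictly increasing 1-minute grid",
                "ckm_format_error")
    }
    start_minute_of_day <- minute[1L] %% 1440L
  } else {
    stamp <- as.POSIXct(time_raw, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                       "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    if (any(is.na(stamp)) || any(diff(as.numeric(stamp)) != 60)) {
      abort_ckm("timestamps are not a strictly increasing 1-minute grid",
                "ckm_format_error")
    }
    minute <- seq_along(stamp) - 1L
    lt <- as.POSIXlt(stamp[1L])
    start_minute_of_day <- lt$hour * 60L + lt$min
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  lux <- num(raw[[cols$lux]])
  activity <- num(raw[[cols$activity]])
  valid <- if (cols$valid %in% names(raw)) {
    v <- tolower(as.character(raw[[cols$valid]]))
    v %in% c("true", "t", "1", "yes")
  } else {
    rep(TRUE, nrow(raw))
  }
  # Preserve the grid: bad cells become invalid minutes, not dropped rows.
  valid <- valid & !is.na(lux) & !is.na(activity) & lux >= 0 & activity >= 0

  out <- tibble::tibble(
    participant_id = as.character(raw[[cols$id]]),
    minute = minute - minute[1L],
    lux = lux,
    activity = activity,
    valid = valid
  )
  attr(out, "start_minute_of_day") <- as.integer(start_minute_of_day)
  out
}

#' Segment a recording into QC-passed, standardized 24-hour day pairs
#'
#' Days are aligned to midnight on the recording's minute grid (a lead-in
#' before the first midnight is discarded). A day whose fraction of valid
#' minutes falls below `min_valid_fraction` is dropped; remaining invalid
#' minutes are linearly interpolated within the day *before* the log
#' transforms (zero-filling would inject spurious 24-h power). Each surviving
#' day is transformed and standardized to zero mean and unit (population)
#' variance; a day with zero variance in either transformed signal (e.g.
#' recorded in constant darkness) is rejected, not an error.
#'
#' @param rec Recording tibble as returned by [load_minute_records()] or
#'   [simulate_actigraphy()] (columns `lux`, `activity`, `valid`).
#' @param minutes_per_day Minutes per day (default 1440).
#' @param min_valid_fraction Minimum fraction of valid minutes for a day to
#'   be retained (default 0.8).
#' @return A nested tibble of surviving days with columns `day_index`,
#'   `valid_fraction`, and list-columns `light_t`, `activity_t` (each a
#'   standardized vector of length `minutes_per_day`). Attributes
#'   `n_days_total`, `n_dropped_qc`, `n_dropped_zero_var` summarise QC.
#' @export
segment_days <- function(rec, minutes_per_day = 1440, min_valid_fraction = 0.8) {
  stopifnot(all(c("lux", "activity", "valid") %in% names(rec)))
  offset <- attr(rec, "start_minute_of_day") %||% 0L
  skip <- (minutes_per_day - offset) %% minutes_per_day
  n_use <- nrow(rec) - skip
  n_days <- n_use %/% minutes_per_day
  if (n_days < 1L) {
    out <- tibble::tibble(day_index = integer(), valid_fraction = numeric(),
                          light_t = list(), activity_t = list())
    attr(out, "n_days_total") <- 0L
    attr(out, "n_dropped_qc") <- 0L
    attr(out, "n_dropped_zero_var") <- 0L
    return(out)
  }

  interp <- function(x, ok) {
    if (all(ok)) return(x)
    if (sum(ok) < 2L) return(rep(NA_real_, length(x)))
    approx(x = which(ok), y = x[ok], xout = seq_along(x), rule = 2)$y
  }

  dropped_qc <- 0L
  dropped_zv <- 0L
  rows <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    idx <- skip + (d - 1L) * minutes_per_day + seq_len(minutes_per_day)
    lux <- rec$lux[idx]
    act <- rec$activity[idx]
    ok <- rec$valid[idx] & !is.na(lux) & !is.na(act)
    vf <- mean(ok)
    if (vf < min_valid_fraction) {
      dropped_qc <- dropped_qc + 1L
      next
    }
    lt <- transform_light(interp(lux, ok))
    at <- transform_activity(interp(act, ok))
    if (anyNA(lt) || anyNA(at) ||
        sd_pop(lt) < 1e-12 || sd_pop(at) < 1e-12) {
      dropped_zv <- dropped_zv + 1L
      next
    }
    rows[[d]] <- tibble::tibble(
      day_index = d,
      valid_fraction = vf,
      light_t = list(standardize_pop(lt)),
      activity_t = list(standardize_pop(at))
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(day_index = integer(), valid_fraction = numeric(),
                          light_t = list(), activity_t = list())
  }
  attr(out, "n_days_total") <- n_days
  attr(out, "n_dropped_qc") <- dropped_qc
  attr(out, "n_dropped_zero_var") <- dropped_zv
  out
}
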