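# broom-style accessors for design-based fits.

#' Tidy a design-based fit
#'
#' @param x A `ckm_svyglm` or `ckm_svycox` object.
#' @param exponentiate Report odds/hazard ratios instead of log effects?
#' @param conf.level Confidence level; intervals use a t reference with the
#'   design degrees of freedom.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.ckm_svyfit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  beta <- x$coef
  se <- sqrt(diag(as.matrix(x$vcov)))
  tstat <- beta / se
  df <- max(x$df_design, 1L)
  tcrit <- qt(1 - (1 - conf.level) / 2, df)
  lo <- beta - tcrit * se
  hi <- beta + tcrit * se
  if (isTRUE(x$separation)) {
    lo[] <- -Inf
    hi[] <- Inf
  }
  out <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(tstat),
    p.value = unname(2 * pt(-abs(tstat), df)),
    conf.low = unname(lo),
    conf.high = unname(hi)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out,
      estimate = exp(.data$estimate),
      conf.low = exp(.data$conf.low),
      conf.high = exp(.data$conf.high)
    )
  }
  out
}

#' @export
tidy.ckm_svyglm <- tidy.ckm_svyfit

#' @export
tidy.ckm_svycox <- tidy.ckm_svyfit

#' Design summary of a fit
#'
#' @param x A `ckm_svyglm` or `ckm_svycox` object.
#' @param ... Unused.
#' @return One-row tibble: sample size, events, design size, weighted
#'   population total, design df, and flags.
#' @export
glance.ckm_svyfit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    events = x$events,
    n_strata = x$n_strata,
    n_psu = x$n_psu,
    df_design = x$df_design,
    population_total = x$sum_weights,
    separation = isTRUE(x$separation),
    n_non_estimable = length(x$non_estimable %||% character())
  )
}

#' @export
glance.ckm_svyglm <- glance.ckm_svyfit

#' @export
glance.ckm_svycox <- glance.ckm_svyfit

#' @export
print.ckm_svyfit <- function(x, ...) {
  kind <- if (inherits(x, "ckm_svycox")) "Cox" else "logistic"
  cat(sprintf(
    "<design-based %s fit> n = %d, events = %d, strata = %d, PSUs = %d\n",
    kind, x$n, x$events, x$n_strata, x$n_psu
  ))
  print(tidy(x, exponentiate = TRUE))
  invisible(x)
}

#' @export
print.ckm_svyglm <- print.ckm_svyfit

#' @export
print.ckm_svycox <- print.ckm_svyfit
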