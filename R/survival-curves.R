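# Predicted survival curves from a weighted Cox fit (weighted Breslow
# baseline), one curve per exposure quartile with covariates held at
# weighted means (numeric) or the weighted modal level (categorical).

#' Predicted survival curves by quartile
#'
#' Computes the weighted Breslow baseline cumulative hazard from a
#' design-based Cox fit and evaluates predicted survival at each quartile
#' level, holding every other covariate at its weighted mean (numeric) or
#' weighted modal level (factor). Curves start at 1, are nonincreasing, and
#' are truncated at the last event time.
#'
#' @param fit A `ckm_svycox` object whose model includes the quartile factor.
#' @param data The data used to fit the model (for the weighted covariate
#'   profile).
#' @param exposure Name of the quartile term used in the model formula.
#' @param weights Name of the weight column in `data`.
#' @return A tibble of class `ckm_survival_curves`: `quartile`,
#'   `time_months`, `survival`.
#' @export
predicted_survival_curves <- function(fit, data, exposure = "quartile",
                                      weights = "weight") {
  stopifnot(inherits(fit, "ckm_svycox"))
  d <- as.data.frame(data)
  w <- d[[weights]]
  tt <- terms(fit$fit)
  vars <- attr(tt, "term.labels")
  covars <- setdiff(vars, exposure)
  if (!exposure %in% vars) {
    abort_ckm(paste0("model does not contain the exposure term '", exposure, "'"),
              "ckm_config_error")
  }

  profile <- lapply(covars, function(v) {
    x <- d[[v]]
    if (is.numeric(x)) {
      sum(w * x, na.rm = TRUE) / sum(w[!is.na(x)])
    } else {
      f <- factor(x)
      tab <- tapply(w, f, sum)
      factor(names(tab)[which.max(tab)], levels = levels(f))
    }
  })
  names(profile) <- covars

  q_levels <- levels(factor(d[[exposure]]))
  newdata <- tibble::as_tibble(c(
    setNames(list(factor(q_levels, levels = levels(factor(d[[exposure]])))),
             exposure),
    lapply(profile, function(p) rep(p, length(q_levels)))
  ))

  sf <- survfit(fit$fit, newdata = as.data.frame(newdata),
                se.fit = FALSE, ctype = 1, stype = 2)
  last_event <- max(fit$fit$y[fit$fit$y[, "status"] == 1, "time"])
  keep <- sf$time <= last_event
  surv <- as.matrix(sf$surv)[keep, , drop = FALSE]

  out <- purrr::map_dfr(seq_along(q_levels), function(j) {
    tibble::tibble(
      quartile = q_levels[j],
      time_months = c(0, sf$time[keep]),
      survival = c(1, surv[, j])
    )
  })
  class(out) <- c("ckm_survival_curves", class(out))
  out
}
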