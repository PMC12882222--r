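# Design-based (Taylor-linearized) variance machinery shared by the weighted
# logistic and Cox fits: influence contributions are summed to PSU totals and
# combined with the stratified between-cluster estimator.

check_design <- function(data, weights, strata, psu, single_psu = "error") {
  for (nm in c(weights, strata, psu)) {
    if (!nm %in% names(data)) {
      abort_ckm(paste0("design column '", nm, "' not found"), "ckm_config_error")
    }
  }
  w <- data[[weights]]
  if (any(is.na(w)) || any(w <= 0)) {
    abort_ckm("sampling weights must be positive and non-missing",
              "ckm_config_error")
  }
  if (single_psu == "error") {
    tab <- tapply(data[[psu]], data[[strata]], function(p) length(unique(p)))
    bad <- names(tab)[tab < 2]
    if (length(bad)) {
      abort_ckm(
        paste0("stratum with a single PSU (variance undefined): ",
               paste(bad, collapse = ", ")),
        "ckm_design_error"
      )
    }
  }
  invisible(TRUE)
}

# Stratified between-PSU variance of a total, applied to per-observation
# influence contributions (n x p). single_psu: "error" (handled upstream),
# "adjust" centers a lone PSU at the grand mean, "remove" drops it.
linearized_vcov <- function(infl, strata, psu, single_psu = c("error", "adjust", "remove")) {
  single_psu <- match.arg(single_psu)
  infl <- as.matrix(infl)
  p <- ncol(infl)
  cl <- interaction(strata, psu, drop = TRUE)
  totals <- rowsum(infl, cl, reorder = FALSE)
  cl_stratum <- tapply(as.character(strata), cl, `[`, 1L)[rownames(totals)]
  grand_mean <- colMeans(totals)

  V <- matrix(0, p, p)
  for (h in unique(cl_stratum)) {
    rows <- which(cl_stratum == h)
    n_h <- length(rows)
    if (n_h == 1L) {
      if (single_psu == "remove") next
      dev <- totals[rows, , drop = FALSE] -
        matrix(grand_mean, 1L, p, byrow = TRUE)
      V <- V + crossprod(dev)
      next
    }
    dev <- sweep(totals[rows, , drop = FALSE], 2L,
                 colMeans(totals[rows, , drop = FALSE]))
    V <- V + n_h / (n_h - 1) * crossprod(dev)
  }
  dimnames(V) <- list(colnames(infl), colnames(infl))
  V
}

design_df <- function(strata, psu) {
  cl <- interaction(strata, psu, drop = TRUE)
  nlevels(cl) - length(unique(strata))
}

#' Survey-weighted logistic regression with design-based variance
#'
#' Fits a weighted maximum pseudo-likelihood logistic model and estimates the
#' covariance of the coefficients by Taylor linearization: per-observation
#' score contributions are premultiplied by the inverse information, summed
#' within primary sampling units (PSUs), and combined with the stratified
#' between-PSU (with-replacement) variance estimator. Confidence intervals
#' use a t reference with design degrees of freedom (#PSUs - #strata).
#'
#' @param data Data frame containing outcome, covariates and design columns.
#' @param formula Model formula, e.g. `advanced_ckm ~ quartile + age + sex`.
#'   To report odds ratios against the highest-magnitude quartile, relevel the
#'   exposure (`stats::relevel(q, ref = "Q4")`) or use [fit_quartile_models()].
#' @param weights,strata,psu Names of the design columns (defaults `"weight"`,
#'   `"stratum"`, `"psu"`).
#' @param single_psu What to do with a stratum contributing a single PSU:
#'   `"error"` (default; names the stratum), `"adjust"` (center at the grand
#'   mean), or `"remove"`.
#' @return An object of class `ckm_svyglm` (also `ckm_svyfit`) with
#'   [tidy()]/[glance()] methods. Separation (non-convergence or runaway
#'   coefficients) is flagged in `$separation`, with the affected terms
#'   reported as non-estimable rather than crashing.
#' @export
weighted_logistic <- function(data, formula, weights = "weight",
                              strata = "stratum", psu = "psu",
                              single_psu = "error") {
  data <- as.data.frame(data)
  mf0 <- model.frame(formula, data, na.action = stats::na.pass)
  keep <- complete.cases(mf0) & complete.cases(data[, c(weights, strata, psu)])
  d <- data[keep, , drop = FALSE]
  check_design(d, weights, strata, psu, single_psu)

  d$.w <- d[[weights]]
  fit <- suppressWarnings(
    glm(formula, family = quasibinomial(), data = d, weights = .w,
        x = TRUE, y = TRUE)
  )
  beta <- coef(fit)
  X <- fit$x
  mu <- fit$fitted.values
  y <- fit$y
  U <- X * (d$.w * (y - mu))
  bread <- summary(fit)$cov.unscaled        # (X' W X)^-1, W = w * mu(1-mu)
  infl <- U %*% bread
  V <- linearized_vcov(infl, d[[strata]], d[[psu]], single_psu)

  separation <- !fit$converged | any(abs(beta) > 15, na.rm = TRUE)
  structure(
    list(
      fit = fit, coef = beta, vcov = V,
      df_design = design_df(d[[strata]], d[[psu]]),
      n = nrow(d), events = sum(y > 0.5),
      sum_weights = sum(d$.w),
      n_strata = length(unique(d[[strata]])),
      n_psu = nlevels(interaction(d[[strata]], d[[psu]], drop = TRUE)),
      separation = separation,
      effect_label = "OR",
      call = match.call()
    ),
    class = c("ckm_svyglm", "ckm_svyfit")
  )
}

#' Survey-weighted Cox proportional-hazards regression
#'
#' Weighted partial-likelihood estimation (Efron ties) via
#' [survival::coxph()], with design-based variance from weighted dfbeta
#' residuals aggregated over PSUs within strata, as for
#' [weighted_logistic()]. Time scale is follow-up months since baseline.
#'
#' @inheritParams weighted_logistic
#' @param formula A formula with a [survival::Surv()] left-hand side, e.g.
#'   `Surv(followup_months, dead) ~ quartile + age`.
#' @return An object of class `ckm_svycox` (also `ckm_svyfit`). Levels with no
#'   events yield `NA` coefficients and are flagged in `$non_estimable`.
#' @export
weighted_cox <- function(data, formula, weights = "weight",
                         strata = "stratum", psu = "psu",
                         single_psu = "error") {
  data <- as.data.frame(data)
  mf0 <- model.frame(formula, data, na.action = stats::na.pass)
  keep <- complete.cases(mf0) & complete.cases(data[, c(weights, strata, psu)])
  d <- data[keep, , drop = FALSE]
  check_design(d, weights, strata, psu, single_psu)

  d$.w <- d[[weights]]
  fit <- suppressWarnings(
    coxph(formula, data = d, weights = .w, ties = "efron",
          model = TRUE, x = TRUE, robust = FALSE)
  )
  beta <- coef(fit)
  non_estimable <- names(beta)[is.na(beta)]
  ok <- !is.na(beta)
  dfbeta <- as.matrix(residuals(fit, type = "dfbeta", weighted = TRUE))
  Vlin <- linearized_vcov(dfbeta, d[[strata]], d[[psu]], single_psu)
  V <- matrix(NA_real_, length(beta), length(beta),
              dimnames = list(names(beta), names(beta)))
  if (ncol(dfbeta) == length(beta)) {
    V[] <- Vlin
    V[!ok, ] <- NA_real_
    V[, !ok] <- NA_real_
  } else if (ncol(dfbeta) == sum(ok)) {
    V[ok, ok] <- Vlin
  }

  structure(
    list(
      fit = fit, coef = beta, vcov = V,
      df_design = design_df(d[[strata]], d[[psu]]),
      n = nrow(d), events = fit$nevent,
      sum_weights = sum(d$.w),
      n_strata = length(unique(d[[strata]])),
      n_psu = nlevels(interaction(d[[strata]], d[[psu]], drop = TRUE)),
      separation = FALSE,
      non_estimable = non_estimable,
      effect_label = "HR",
      call = match.call()
    ),
    class = c("ckm_svycox", "ckm_svyfit")
  )
}

#' Premature-mortality Cox model (death before attained age 70)
#'
#' The event is death before attained age 70; follow-up is administratively
#' censored at the month the participant turns 70, and participants already
#' aged 70+ at baseline are excluded. Otherwise identical to [weighted_cox()].
#'
#' @inheritParams weighted_cox
#' @param rhs Right-hand side of the model, e.g. `~ quartile + age + sex`.
#' @param age,followup,dead,age_at_exit Names of the baseline-age,
#'   follow-up-months, death-indicator and age-at-exit columns.
#' @return A `ckm_svycox` object.
#' @export
premature_death_model <- function(data, rhs, weights = "weight",
                                  strata = "stratum", psu = "psu",
                                  age = "age", followup = "followup_months",
                                  dead = "dead", age_at_exit = "age_at_exit",
                                  single_psu = "error") {
  d <- dplyr::filter(as.data.frame(data), .data[[age]] < 70)
  months_to_70 <- (70 - d[[age]]) * 12
  d$.pd_event <- fired(d[[dead]] & d[[age_at_exit]] < 70)
  d$.pd_time <- pmin(d[[followup]], months_to_70)
  d$.pd_time[is.na(d[[followup]])] <- NA_real_
  f <- as.formula(paste("Surv(.pd_time, .pd_event)", paste(deparse(rhs), collapse = "")))
  weighted_cox(d, f, weights = weights, strata = strata, psu = psu,
               single_psu = single_psu)
}
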