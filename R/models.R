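# Sequential adjustment models and the forest-table builder.

#' Covariate sets of the sequential adjustment models
#'
#' Model 1 is unadjusted; Model 2 adds demographics (age, sex, race,
#' education, household income); Model 3 adds lifestyle (smoking, weekly
#' alcohol consumption); Model 4 adds clinical covariates (hypertension,
#' diabetes). The sets are nested by construction.
#'
#' @param model Integer 1-4.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model) {
  stopifnot(model %in% 1:4)
  m2 <- c("age", "sex", "race", "education", "income")
  m3 <- c(m2, "smoking", "alcohol")
  m4 <- c(m3, "hypertension", "diabetes")
  list(character(0), m2, m3, m4)[[model]]
}

outcome_spec <- function(outcome) {
  switch(outcome,
    advanced = list(type = "logistic", lhs = "advanced_ckm"),
    allcause = list(type = "cox", lhs = "Surv(followup_months, dead)"),
    cvd = list(type = "cox", lhs = "Surv(followup_months, cvd_death)"),
    premature = list(type = "premature", lhs = NULL),
    abort_ckm(paste0("unknown outcome '", outcome, "'"), "ckm_config_error")
  )
}

#' Quartile forest table across sequential adjustment models
#'
#' Fits the requested outcome against phasor-magnitude quartiles (reference =
#' Q4, the best-aligned group) under Models 1-4 and returns a tidy forest
#' table of per-quartile odds/hazard ratios. Outcomes: `"advanced"`
#' (design-based logistic for advanced CKM), `"allcause"` and `"cvd"`
#' (design-based Cox; CVD treats non-CVD deaths as censoring, i.e. a
#' cause-specific hazard), `"premature"` (death before attained age 70 via
#' [premature_death_model()]).
#'
#' @param data Analysis tibble with `quartile`, outcome and covariate columns
#'   (see [simulate_cohort()] for the dictionary).
#' @param outcome One of `"advanced"`, `"allcause"`, `"cvd"`, `"premature"`.
#' @param models Integer vector of adjustment models to fit (subset of 1:4).
#' @param exposure Name of the quartile factor column.
#' @inheritParams weighted_logistic
#' @param drop_covariates Covariates to remove from every adjustment set
#'   (used by [stratified_fits()] for the stratifying variable).
#' @return A tibble of class `ckm_forest`: `outcome`, `model`, `term`,
#'   `estimate` (OR/HR), `conf.low`, `conf.high`, `std.error`, `p.value`,
#'   `n`, `events`, `effect`.
#' @export
fit_quartile_models <- function(data, outcome = "advanced", models = 1:4,
                                exposure = "quartile",
                                weights = "weight", strata = "stratum",
                                psu = "psu", single_psu = "error",
                                drop_covariates = character()) {
  spec <- outcome_spec(outcome)
  d <- as.data.frame(data)
  d$.q <- stats::relevel(factor(d[[exposure]]), ref = "Q4")

  purrr::map_dfr(models, function(m) {
    covs <- setdiff(model_covariates(m), drop_covariates)
    rhs <- paste(c(".q", covs), collapse = " + ")
    fit <- switch(spec$type,
      logistic = weighted_logistic(
        d, as.formula(paste(spec$lhs, "~", rhs)),
        weights, strata, psu, single_psu
      ),
      cox = weighted_cox(
        d, as.formula(paste(spec$lhs, "~", rhs)),
        weights, strata, psu, single_psu
      ),
      premature = premature_death_model(
        d, as.formula(paste("~", rhs)),
        weights = weights, strata = strata, psu = psu, single_psu = single_psu
      )
    )
    tidy(fit, exponentiate = TRUE) |>
      dplyr::filter(grepl("^\\.q", .data$term)) |>
      dplyr::mutate(
        term = sub("^\\.q", "", .data$term),
        outcome = outcome,
        model = m,
        n = fit$n,
        events = fit$events,
        effect = fit$effect_label
      ) |>
      dplyr::select("outcome", "model", "term", "estimate", "conf.low",
                    "conf.high", "std.error", "p.value", "n", "events",
                    "effect")
  }) |>
    (\(x) { class(x) <- c("ckm_forest", class(x)); x })()
}

#' Subgroup (stratified) fits by age band and sex
#'
#' Refits a quartile model within baseline-age bands (20-39, 40-59, >= 60
#' years) and within sex, returning one forest row-set per subgroup.
#' Subgroups may leave design strata with a single PSU, so lone PSUs are
#' grand-mean-centered by default (`single_psu = "adjust"`); empty subgroups
#' are skipped with a message.
#'
#' @inheritParams fit_quartile_models
#' @param model Which adjustment model to use (default 4).
#' @param age_breaks Lower bounds of the age bands plus `Inf`.
#' @param sex_col,age_col Column names.
#' @return A tibble like [fit_quartile_models()] output with extra columns
#'   `subgroup_var`, `subgroup`.
#' @export
stratified_fits <- function(data, outcome = "advanced", model = 4,
                            exposure = "quartile",
                            age_breaks = c(20, 40, 60, Inf),
                            age_col = "age", sex_col = "sex",
                            weights = "weight", strata = "stratum",
                            psu = "psu", single_psu = "adjust") {
  d <- as.data.frame(data)
  bands <- cut(d[[age_col]], breaks = age_breaks, right = FALSE,
               include.lowest = TRUE)
  subgroups <- c(
    setNames(lapply(levels(bands), function(l) !is.na(bands) & bands == l),
             paste0("age:", levels(bands))),
    setNames(lapply(unique(as.character(d[[sex_col]])),
                    function(l) !is.na(d[[sex_col]]) & d[[sex_col]] == l),
             paste0("sex:", unique(as.character(d[[sex_col]]))))
  )

  # Within a subgroup, drop the stratifying covariate from the adjustment set.
  purrr::imap_dfr(subgroups, function(keep, label) {
    if (sum(keep) == 0L) {
      message("stratified_fits: empty subgroup ", label, " skipped")
      return(NULL)
    }
    var <- sub(":.*$", "", label)
    res <- tryCatch(
      fit_quartile_models(d[keep, , drop = FALSE], outcome = outcome,
                          models = model, exposure = exposure,
                          weights = weights, strata = strata, psu = psu,
                          single_psu = single_psu,
                          drop_covariates = if (var == "sex") sex_col else character()),
      error = function(e) {
        message("stratified_fits: subgroup ", label, " failed: ",
                conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) return(NULL)
    dplyr::mutate(res, subgroup_var = var,
                  subgroup = sub("^[^:]*:", "", label))
  })
}
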