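# Cardio-kidney-metabolic (CKM) staging: eGFR, KDIGO CKD risk, metabolic
# syndrome, and the deterministic stage 0-4 rules.

#' Estimated GFR (CKD-EPI 2021, race-free creatinine equation)
#'
#' `eGFR = 142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age *
#' 1.012[female]`, with `k = 0.7` (female) / `0.9` (male) and `a = -0.241`
#' (female) / `-0.302` (male).
#'
#' @param scr_mg_dl Serum creatinine in mg/dL (> 0).
#' @param age Age in years (>= 18).
#' @param sex `"female"`/`"male"` (character or factor), recycled as needed.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckd_epi_2021 <- function(scr_mg_dl, age, sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male") | is.na(sex))) {
    abort_ckm("sex must be 'female' or 'male'", "ckm_domain_error")
  }
  if (any(scr_mg_dl <= 0, na.rm = TRUE) || any(age < 18, na.rm = TRUE)) {
    abort_ckm("serum creatinine must be positive and age >= 18",
              "ckm_domain_error")
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  ratio <- scr_mg_dl / kappa
  142 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.200 * 0.9938^age *
    ifelse(female, 1.012, 1)
}

#' KDIGO eGFR (G) and albuminuria (A) stages
#'
#' G stages: G1 >= 90, G2 60-89, G3a 45-59, G3b 30-44, G4 15-29, G5 < 15
#' (lower bounds inclusive). A stages from the urine albumin-to-creatinine
#' ratio (mg/g): A1 < 30, A2 30-300 (both bounds inclusive), A3 > 300.
#' Missing input yields `NA` ("unstageable"), which the staging missing-data
#' policy handles downstream.
#'
#' @param egfr eGFR in mL/min/1.73 m^2.
#' @param uacr_mg_g Urine albumin-to-creatinine ratio, mg/g.
#' @return Factor `G1`-`G5` / `A1`-`A3`.
#' @export
kdigo_g_stage <- function(egfr) {
  if (any(egfr < 0, na.rm = TRUE)) {
    abort_ckm("eGFR must be nonnegative", "ckm_domain_error")
  }
  cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf), right = FALSE,
      labels = c("G5", "G4", "G3b", "G3a", "G2", "G1")) |>
    factor(levels = c("G1", "G2", "G3a", "G3b", "G4", "G5"))
}

#' @rdname kdigo_g_stage
#' @export
kdigo_a_stage <- function(uacr_mg_g) {
  if (any(uacr_mg_g < 0, na.rm = TRUE)) {
    abort_ckm("UACR must be nonnegative", "ckm_domain_error")
  }
  factor(
    ifelse(is.na(uacr_mg_g), NA_character_,
           ifelse(uacr_mg_g < 30, "A1",
                  ifelse(uacr_mg_g <= 300, "A2", "A3"))),
    levels = c("A1", "A2", "A3")
  )
}

# KDIGO 2012 prognosis heat map, transcribed cell by cell.
kdigo_matrix <- local({
  m <- matrix(NA_character_, nrow = 6, ncol = 3,
              dimnames = list(c("G1", "G2", "G3a", "G3b", "G4", "G5"),
                              c("A1", "A2", "A3")))
  m["G1", ] <- c("low", "moderate", "high")
  m["G2", ] <- c("low", "moderate", "high")
  m["G3a", ] <- c("moderate", "high", "very_high")
  m["G3b", ] <- c("high", "very_high", "very_high")
  m["G4", ] <- c("very_high", "very_high", "very_high")
  m["G5", ] <- c("very_high", "very_high", "very_high")
  m
})

#' KDIGO CKD prognosis risk category
#'
#' Cross-classifies the G and A stages on the standard KDIGO heat map into
#' low / moderate / high / very high risk. `NA` in either stage propagates.
#'
#' @param g_stage,a_stage Factors/characters as returned by
#'   [kdigo_g_stage()] / [kdigo_a_stage()].
#' @return Factor with levels `low`, `moderate`, `high`, `very_high`.
#' @export
kdigo_risk <- function(g_stage, a_stage) {
  g <- as.character(g_stage)
  a <- as.character(a_stage)
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g) & !is.na(a)
  out[ok] <- kdigo_matrix[cbind(g[ok], a[ok])]
  factor(out, levels = c("low", "moderate", "high", "very_high"))
}

#' Metabolic syndrome (harmonized ATP-III rule)
#'
#' At least 3 of: waist >= 88 cm (female) / 102 cm (male); triglycerides
#' >= 150 mg/dL; HDL < 50 (female) / < 40 (male) mg/dL; BP >= 130/85 mmHg or
#' antihypertensive treatment; fasting glucose >= 100 mg/dL or antidiabetic
#' treatment. All `>=` comparisons are inclusive. With missing components the
#' call is decided when it can be (>= 3 present components satisfied, or too
#' few satisfiable), otherwise `NA`.
#'
#' @param data Data frame with (any of) `sex`, `waist_cm`,
#'   `triglycerides_mg_dl`, `hdl_mg_dl`, `sbp`, `dbp`,
#'   `on_antihypertensive_rx`, `fpg_mg_dl`, `on_antidiabetic_rx`.
#' @return Logical vector, one element per row.
#' @export
has_metabolic_syndrome <- function(data) {
  col <- function(nm) if (nm %in% names(data)) data[[nm]] else rep(NA, nrow(data))
  female <- tolower(as.character(col("sex"))) == "female"
  comp <- cbind(
    wc = col("waist_cm") >= ifelse(female, 88, 102),
    tg = col("triglycerides_mg_dl") >= 150,
    hdl = col("hdl_mg_dl") < ifelse(female, 50, 40),
    bp = {
      bp <- col("sbp") >= 130 | col("dbp") >= 85
      rx <- col("on_antihypertensive_rx")
      ifelse(fired(bp) | fired(rx), TRUE,
             ifelse(is.na(bp) | is.na(rx), NA, FALSE))
    },
    glu = {
      g <- col("fpg_mg_dl") >= 100
      rx <- col("on_antidiabetic_rx")
      ifelse(fired(g) | fired(rx), TRUE,
             ifelse(is.na(g) | is.na(rx), NA, FALSE))
    }
  )
  n_true <- rowSums(comp, na.rm = TRUE)
  n_miss <- rowSums(is.na(comp))
  ifelse(n_true >= 3, TRUE, ifelse(n_true + n_miss < 3, FALSE, NA))
}

#' CKM syndrome staging (stages 0-4)
#'
#' Deterministic rule-based staging on the cardio-kidney-metabolic continuum,
#' evaluated per row of a clinical table. The assigned stage is the maximum
#' over all satisfied stage rules:
#'
#' * **Stage 4** - history of clinical cardiovascular disease.
#' * **Stage 3** - very-high-risk CKD (KDIGO), or an elevated 10-year CVD
#'   risk flag (supplied precomputed via `ten_year_cvd_risk_elevated`; the
#'   risk equation itself is pluggable and defaults to absent/false).
#' * **Stage 2** - triglycerides >= 135 mg/dL, hypertension, diabetes,
#'   metabolic syndrome, or moderate/high-risk CKD.
#' * **Stage 1** - BMI >= 25 kg/m^2, waist >= 88 cm (female) / 102 cm (male),
#'   or prediabetes (fasting glucose 100-124 mg/dL, HbA1c 5.7-6.4 %, or
#'   antidiabetic therapy).
#' * **Stage 0** - none of the above.
#'
#' Advanced CKM = stages 3-4. A rule with missing inputs is simply not fired;
#' a row where no rule fires *and* no stage 1-4 rule is evaluable is
#' unstageable (`NA` stage) and should be excluded downstream.
#'
#' @param data Clinical tibble; recognised columns: `sex`, `age`, `waist_cm`,
#'   `bmi`, `fpg_mg_dl`, `hba1c_pct`, `on_antidiabetic_rx`,
#'   `triglycerides_mg_dl`, `hdl_mg_dl`, `sbp`, `dbp`,
#'   `on_antihypertensive_rx`, `hypertension`, `diabetes`, `scr_mg_dl`,
#'   `uacr_mg_g`, `cvd_history`, `ten_year_cvd_risk_elevated`.
#' @param antidiabetic_rx_is_prediabetes Treat antidiabetic therapy as a
#'   stage-1 prediabetes qualifier (as the staging rules print it). Set
#'   `FALSE` to restrict the prediabetes rule to glycemia.
#' @return The input with added columns `egfr`, `kdigo_g`, `kdigo_a`,
#'   `ckd_risk`, `ckm_stage` (integer 0-4, `NA` = unstageable), `advanced_ckm`
#'   (logical) and `ckm_rules` (comma-separated fired rule ids).
#' @export
#' @examples
#' ckm_stage(tibble::tibble(sex = "female", age = 45, waist_cm = 80,
#'                          bmi = 23))$ckm_stage
ckm_stage <- function(data, antidiabetic_rx_is_prediabetes = TRUE) {
  n <- nrow(data)
  col <- function(nm) if (nm %in% names(data)) data[[nm]] else rep(NA, n)
  female <- tolower(as.character(col("sex"))) == "female"

  egfr <- rep(NA_real_, n)
  scr <- col("scr_mg_dl")
  age <- col("age")
  ok <- !is.na(scr) & !is.na(age) & !is.na(female) & scr > 0 & age >= 18
  if (any(ok)) {
    egfr[ok] <- egfr_ckd_epi_2021(scr[ok], age[ok],
                                  ifelse(female[ok], "female", "male"))
  }
  g <- kdigo_g_stage(egfr)
  a <- kdigo_a_stage(col("uacr_mg_g"))
  risk <- kdigo_risk(g, a)
  mets <- has_metabolic_syndrome(data)

  prediab <- {
    p_fpg <- col("fpg_mg_dl") >= 100 & col("fpg_mg_dl") <= 124
    p_a1c <- col("hba1c_pct") >= 5.7 & col("hba1c_pct") <= 6.4
    p_rx <- if (antidiabetic_rx_is_prediabetes) col("on_antidiabetic_rx") else rep(NA, n)
    ifelse(fired(p_fpg) | fired(p_a1c) | fired(p_rx), TRUE,
           ifelse(is.na(p_fpg) & is.na(p_a1c) & is.na(p_rx), NA, FALSE))
  }

  rules <- list(
    s4_cvd_history  = list(4L, col("cvd_history")),
    s3_very_high_ckd = list(3L, risk == "very_high"),
    s3_cvd_risk     = list(3L, col("ten_year_cvd_risk_elevated")),
    s2_tg           = list(2L, col("triglycerides_mg_dl") >= 135),
    s2_hypertension = list(2L, col("hypertension")),
    s2_diabetes     = list(2L, col("diabetes")),
    s2_metabolic_syndrome = list(2L, mets),
    s2_mod_high_ckd = list(2L, risk %in% c("moderate", "high") &
                                !is.na(risk)),
    s1_bmi          = list(1L, col("bmi") >= 25),
    s1_waist        = list(1L, col("waist_cm") >= ifelse(female, 88, 102)),
    s1_prediabetes  = list(1L, prediab)
  )
  # s2_mod_high_ckd: %in% maps NA to FALSE; restore NA when risk is unknown
  rules$s2_mod_high_ckd[[2]][is.na(risk)] <- NA

  fired_mat <- vapply(rules, function(r) fired(r[[2]]), logical(n))
  eval_mat <- vapply(rules, function(r) !is.na(r[[2]]), logical(n))
  if (n == 1L) {
    fired_mat <- matrix(fired_mat, nrow = 1, dimnames = list(NULL, names(rules)))
    eval_mat <- matrix(eval_mat, nrow = 1, dimnames = list(NULL, names(rules)))
  }
  stage_of <- vapply(rules, `[[`, integer(1), 1L)

  stage <- apply(fired_mat, 1L, function(f) {
    if (any(f)) max(stage_of[f]) else 0L
  })
  none_evaluable <- rowSums(eval_mat) == 0L
  unstageable <- stage == 0L & none_evaluable
  stage[unstageable] <- NA_integer_

  rule_str <- apply(fired_mat, 1L, function(f) {
    paste(names(rules)[f], collapse = ",")
  })
  rule_str[unstageable] <- NA_character_

  dplyr::mutate(
    tibble::as_tibble(data),
    egfr = egfr,
    kdigo_g = g,
    kdigo_a = a,
    ckd_risk = risk,
    ckm_stage = as.integer(stage),
    advanced_ckm = .data$ckm_stage >= 3L,
    ckm_rules = rule_str
  )
}
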