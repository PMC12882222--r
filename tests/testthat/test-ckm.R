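# CKM staging: eGFR equation, KDIGO categories, metabolic syndrome, and the
# stage 0-4 rules.

test_that("CKD-EPI 2021 equation matches direct evaluation and is well behaved", {
  # independent transcription of the published equation for a worked case
  expected_f50 <- 142 * min(0.8 / 0.7, 1)^-0.241 * max(0.8 / 0.7, 1)^-1.200 *
    0.9938^50 * 1.012
  expect_equal(egfr_ckd_epi_2021(0.8, 50, "female"), expected_f50,
               tolerance = 1e-12)
  expect_equal(expected_f50, 89.68, tolerance = 1e-3)

  expected_m40_low <- 142 * (0.6 / 0.9)^-0.302 * 0.9938^40
  expect_equal(egfr_ckd_epi_2021(0.6, 40, "male"), expected_m40_low,
               tolerance = 1e-12)

  # continuity at the sex-specific kappa knot
  eps <- 1e-9
  expect_equal(egfr_ckd_epi_2021(0.9 - eps, 60, "male"),
               egfr_ckd_epi_2021(0.9 + eps, 60, "male"), tolerance = 1e-6)
  expect_equal(egfr_ckd_epi_2021(0.7 - eps, 60, "female"),
               egfr_ckd_epi_2021(0.7 + eps, 60, "female"), tolerance = 1e-6)

  # strictly decreasing in creatinine
  scr <- seq(0.3, 5, by = 0.1)
  expect_true(all(diff(egfr_ckd_epi_2021(scr, 55, "female")) < 0))
  expect_gt(egfr_ckd_epi_2021(1, 50, "male"),
            egfr_ckd_epi_2021(2, 50, "male"))
  expect_error(egfr_ckd_epi_2021(0, 50, "male"), class = "ckm_domain_error")
  expect_error(egfr_ckd_epi_2021(1, 15, "male"), class = "ckm_domain_error")
})

test_that("KDIGO G/A boundaries are as stated", {
  expect_equal(as.character(kdigo_g_stage(c(90, 89.9, 60, 59.9, 45, 44.9,
                                            30, 29.9, 15, 14.9))),
               c("G1", "G2", "G2", "G3a", "G3a", "G3b",
                 "G3b", "G4", "G4", "G5"))
  expect_equal(as.character(kdigo_a_stage(c(0, 29.9, 30, 300, 300.1))),
               c("A1", "A1", "A2", "A2", "A3"))
  expect_true(is.na(kdigo_a_stage(NA)))
})

test_that("the full KDIGO risk heat map is transcribed correctly", {
  expected <- rbind(
    G1 = c("low", "moderate", "high"),
    G2 = c("low", "moderate", "high"),
    G3a = c("moderate", "high", "very_high"),
    G3b = c("high", "very_high", "very_high"),
    G4 = c("very_high", "very_high", "very_high"),
    G5 = c("very_high", "very_high", "very_high")
  )
  colnames(expected) <- c("A1", "A2", "A3")
  for (g in rownames(expected)) {
    for (a in colnames(expected)) {
      expect_equal(as.character(kdigo_risk(g, a)), expected[g, a],
                   info = paste(g, a))
    }
  }
  expect_true(is.na(kdigo_risk("G1", NA)))
})

test_that("metabolic syndrome counts components with inclusive thresholds", {
  base <- tibble::tibble(
    sex = "male", waist_cm = 90, triglycerides_mg_dl = 100, hdl_mg_dl = 50,
    sbp = 118, dbp = 70, on_antihypertensive_rx = FALSE,
    fpg_mg_dl = 90, on_antidiabetic_rx = FALSE
  )
  expect_false(has_metabolic_syndrome(base))
  two <- dplyr::mutate(base, triglycerides_mg_dl = 150, hdl_mg_dl = 39)
  expect_false(has_metabolic_syndrome(two))
  three <- dplyr::mutate(two, fpg_mg_dl = 100)
  expect_true(has_metabolic_syndrome(three))
  # all five components borderline-equal: inclusive comparisons fire
  borderline <- tibble::tibble(
    sex = "female", waist_cm = 88, triglycerides_mg_dl = 150,
    hdl_mg_dl = 49.9, sbp = 130, dbp = 85, on_antihypertensive_rx = FALSE,
    fpg_mg_dl = 100, on_antidiabetic_rx = FALSE
  )
  expect_true(has_metabolic_syndrome(borderline))
})

test_that("worked profiles map to stages 0 through 4", {
  profiles <- tibble::tibble(
    sex = c("female", "male", "male", "male", "female"),
    age = c(45, 50, 50, 60, 62),
    waist_cm = c(80, 95, 95, 95, 90),
    bmi = c(23, 27, 24, 24, 24),
    fpg_mg_dl = c(90, 110, 90, 90, 90),
    hba1c_pct = c(5.2, 5.5, 5.2, 5.2, 5.2),
    on_antidiabetic_rx = FALSE,
    triglycerides_mg_dl = c(100, 100, 140, 100, 100),
    hdl_mg_dl = c(60, 55, 55, 55, 60),
    sbp = 115, dbp = 70, on_antihypertensive_rx = FALSE,
    hypertension = FALSE, diabetes = FALSE,
    scr_mg_dl = c(0.7, 0.9, 0.9, 3.2, 0.8),
    uacr_mg_g = c(5, 5, 5, 10, 8),
    cvd_history = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    ten_year_cvd_risk_elevated = FALSE
  )
  staged <- ckm_stage(profiles)
  expect_equal(staged$ckm_stage, 0:4)
  expect_equal(staged$advanced_ckm, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # the stage-3 row qualifies through G4 kidney disease
  expect_equal(as.character(staged$kdigo_g[4]), "G4")
  expect_match(staged$ckm_rules[4], "s3_very_high_ckd")
  expect_match(staged$ckm_rules[5], "s4_cvd_history")
})

test_that("staging is total and deterministic on complete profiles", {
  set.seed(42)
  p <- random_profiles(10000, complete = TRUE)
  s1 <- ckm_stage(p)
  expect_true(all(s1$ckm_stage %in% 0:4))
  expect_false(anyNA(s1$ckm_stage))
  s2 <- ckm_stage(p)
  expect_identical(s1$ckm_stage, s2$ckm_stage)
})

test_that("adding a risk factor never lowers the stage (monotone dominance)", {
  set.seed(43)
  p <- random_profiles(10000, complete = FALSE, miss = 0.2)
  base <- ckm_stage(p)$ckm_stage
  escalations <- list(
    function(d) dplyr::mutate(d, cvd_history = TRUE),
    function(d) dplyr::mutate(d, scr_mg_dl = 4.5),
    function(d) dplyr::mutate(d, uacr_mg_g = 800),
    function(d) dplyr::mutate(d, ten_year_cvd_risk_elevated = TRUE),
    function(d) dplyr::mutate(d, triglycerides_mg_dl = 200),
    function(d) dplyr::mutate(d, hypertension = TRUE),
    function(d) dplyr::mutate(d, diabetes = TRUE),
    function(d) dplyr::mutate(d, bmi = pmax(bmi, 26, na.rm = TRUE)),
    function(d) dplyr::mutate(d, fpg_mg_dl = 115),
    function(d) dplyr::mutate(d, hba1c_pct = 6.0)
  )
  for (esc in escalations) {
    after <- ckm_stage(esc(p))$ckm_stage
    both <- !is.na(base) & !is.na(after)
    expect_true(all(after[both] >= base[both]))
    # escalation can stage a previously unstageable profile, never the reverse
    expect_false(any(is.na(after) & !is.na(base)))
  }
})

test_that("missing-data policy: rules with missing inputs do not fire; empty profiles are unstageable", {
  p <- tibble::tibble(
    sex = c("female", "female", "male"),
    age = c(50, 50, 55),
    waist_cm = c(80, NA, NA),
    bmi = c(NA, NA, NA),
    triglycerides_mg_dl = c(NA, NA, NA),
    cvd_history = c(NA, NA, TRUE)
  )
  staged <- ckm_stage(p)
  expect_equal(staged$ckm_stage[1], 0L)        # waist evaluable and below cut
  expect_true(is.na(staged$ckm_stage[2]))      # nothing evaluable
  expect_equal(staged$ckm_stage[3], 4L)        # CVD history fires regardless
})

test_that("advanced prevalence of the tuned simulator sits in a plausible band", {
  co <- simulate_cohort(n = 4000, seed = 99)
  staged <- ckm_stage(co)
  expect_identical(staged$advanced_ckm, co$advanced_ckm)
  expect_gt(mean(staged$advanced_ckm), 0.10)
  expect_lt(mean(staged$advanced_ckm), 0.30)
})
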