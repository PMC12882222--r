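# Phasor core: circular cross-correlation, 24-h component, magnitude and
# acrophase conventions.

test_that("circular cross-correlation matches the brute-force loop and its identities", {
  set.seed(11)
  for (n in c(24, 144, 1440)) {
    x <- random_standardized(n)
    y <- random_standardized(n)
    expect_lt(max(abs(circular_xcorr(x, y) - naive_xcorr(x, y))), 1e-10)
  }
  x <- random_standardized(240)
  expect_equal(circular_xcorr(x, x)[1], 1, tolerance = 1e-12)
  expect_equal(circular_xcorr(x, -x)[1], -1, tolerance = 1e-12)
  # shifting y by k minutes puts the correlation peak at lag k
  k <- 37
  y <- x[((seq_along(x) - 1 - k) %% length(x)) + 1]
  expect_equal(which.max(circular_xcorr(x, y)) - 1L, k)
  expect_error(circular_xcorr(x, x[-1]), class = "ckm_domain_error")
  expect_error(circular_xcorr(x, x * 3), class = "ckm_domain_error")
})

test_that("24-hour component obeys the Fourier identities", {
  n <- 1440
  tau <- 0:(n - 1)
  expect_equal(fundamental_component(cos(2 * pi * tau / n)), 1 + 0i,
               tolerance = 1e-12)
  delta <- 200
  P <- fundamental_component(cos(2 * pi * (tau - delta) / n))
  expect_equal(Arg(P), -2 * pi * delta / n, tolerance = 1e-9)
  expect_equal(Mod(fundamental_component(rep(0.37, n))), 0, tolerance = 1e-12)
})

test_that("phase-locked sinusoids give magnitude 1 and the stated sign convention", {
  res0 <- compute_phasor(sinusoid_days(7, lag_minutes = 0))
  expect_equal(res0$magnitude, 1, tolerance = 1e-9)
  expect_equal(res0$acrophase_hours, 0, tolerance = 1e-9)

  # activity lagging light by +2 h is a positive acrophase (evening preference)
  res2 <- compute_phasor(sinusoid_days(7, lag_minutes = 120))
  expect_equal(res2$acrophase_hours, 2, tolerance = 1e-9)
  expect_equal(res2$magnitude, 1, tolerance = 1e-9)

  resm <- compute_phasor(sinusoid_days(7, lag_minutes = -300))
  expect_equal(resm$acrophase_hours, -5, tolerance = 1e-9)
})

test_that("lag equivariance and time-origin invariance hold", {
  rot <- function(v, k) v[((seq_along(v) - 1 - k) %% length(v)) + 1]
  base <- compute_phasor(sinusoid_days(5, lag_minutes = 60))
  # shifting only activity by +k minutes adds k/60 hours
  for (k in c(90, 300)) {
    days <- sinusoid_days(5, lag_minutes = 60)
    days$activity_t <- lapply(days$activity_t, rot, k = k)
    shifted <- compute_phasor(days)
    expect_equal(shifted$acrophase_hours,
                 wrap_half_day(base$acrophase_hours + k / 60),
                 tolerance = 1e-9)
    expect_equal(shifted$magnitude, base$magnitude, tolerance = 1e-9)
  }
  # rotating both signals by the same offset changes nothing
  set.seed(21)
  days <- sinusoid_days(4, lag_minutes = 45)
  days$activity_t <- lapply(days$activity_t,
                            function(v) random_standardized(length(v)))
  ref <- compute_phasor(days)
  rotd <- days
  rotd$light_t <- lapply(rotd$light_t, rot, k = 777)
  rotd$activity_t <- lapply(rotd$activity_t, rot, k = 777)
  res <- compute_phasor(rotd)
  expect_equal(res$magnitude, ref$magnitude, tolerance = 1e-9)
  expect_equal(wrap_half_day(res$acrophase_hours - ref$acrophase_hours), 0,
               tolerance = 1e-9)
})

test_that("magnitude respects the 4/pi bound and day-averaging linearity", {
  set.seed(31)
  for (i in 1:20) {
    days <- sinusoid_days(3)
    days$light_t <- lapply(days$light_t,
                           function(v) random_standardized(length(v)))
    days$activity_t <- lapply(days$activity_t,
                              function(v) random_standardized(length(v)))
    res <- compute_phasor(days, min_days = 3, per_day = TRUE)
    expect_lte(res$magnitude, 4 / pi + 1e-12)
    expect_equal(res$phasor, mean(res$per_day_phasors), tolerance = 1e-12)
    expect_equal(res$magnitude, Mod(res$phasor), tolerance = 1e-15)
  }
  # square-wave correlation attains the bound
  n <- 1440
  sq <- sign(cos(2 * pi * (0:(n - 1)) / n))
  expect_equal(Mod(2 * fft(sq)[[2]] / n), 4 / pi, tolerance = 1e-3)
})

test_that("aggregation methods agree for stationary days and exclusion signals work", {
  days <- sinusoid_days(6, lag_minutes = 120)
  avg <- compute_phasor(days, method = "average_days")
  cat_ <- compute_phasor(days, method = "concatenated")
  expect_equal(cat_$magnitude, avg$magnitude, tolerance = 1e-9)
  expect_equal(cat_$acrophase_hours, avg$acrophase_hours, tolerance = 1e-9)

  excluded <- compute_phasor(days[0, ], min_days = 4)
  expect_true(excluded$excluded)
  expect_true(is.na(excluded$magnitude))
  expect_match(excluded$reason, "fewer than 4")
  expect_true(compute_phasor(days[1:3, ], min_days = 4)$excluded)
})

test_that("quartile assignment cuts at weighted percentiles with lower-tie rule", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q$labels),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  expect_equal(q$cutpoints, c(2, 4, 6))

  # loading weight onto the top half pushes the cutpoints upward
  x <- seq(0.1, 0.8, by = 0.1)
  w_hi <- c(rep(1, 4), rep(10, 4))
  expect_true(all(assign_quartiles(x, w_hi)$cutpoints >
                    assign_quartiles(x)$cutpoints))

  expect_error(assign_quartiles(rep(0.3, 10)), class = "ckm_degenerate_grouping")
  expect_error(assign_quartiles(c(1, 2, 3)), class = "ckm_degenerate_grouping")
})
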