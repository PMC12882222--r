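# Design-based estimation: degenerate-design equivalences, closed-form
# checks, the linearized variance, splines, and weighted descriptives.

test_that("with equal weights and independent PSUs the logistic fit collapses to the classical one", {
  set.seed(50)
  n <- 400
  d <- iid_design(tibble::tibble(
    x = rnorm(n),
    g = factor(sample(c("a", "b"), n, TRUE))
  ))
  d$y <- rbinom(n, 1, plogis(-0.5 + log(2) * d$x + 0.3 * (d$g == "b")))

  sv <- weighted_logistic(d, y ~ x + g)
  ml <- glm(y ~ x + g, family = binomial(), data = d)
  expect_equal(unname(sv$coef), unname(coef(ml)), tolerance = 1e-6)

  # linearized variance equals the HC0 sandwich up to the n/(n-1) factor
  hc0 <- sandwich::vcovHC(ml, type = "HC0")
  expect_equal(unname(sv$vcov), unname(hc0 * n / (n - 1)), tolerance = 1e-6)
})

test_that("a saturated weighted 2x2 logistic reproduces the weighted cross-product odds ratio", {
  d <- tibble::tibble(
    y = c(1, 1, 0, 0, 1, 1, 0, 0),
    x = c(1, 0, 1, 0, 1, 0, 1, 0),
    weight = c(3, 2, 5, 7, 1, 4, 2, 6),
    stratum = rep(c("s1", "s2"), each = 4),
    psu = c(1, 2, 1, 2, 1, 2, 1, 2)
  )
  fit <- weighted_logistic(d, y ~ x)
  w11 <- sum(d$weight[d$y == 1 & d$x == 1])
  w10 <- sum(d$weight[d$y == 1 & d$x == 0])
  w01 <- sum(d$weight[d$y == 0 & d$x == 1])
  w00 <- sum(d$weight[d$y == 0 & d$x == 0])
  expect_equal(unname(fit$coef["x"]), log((w11 * w00) / (w10 * w01)),
               tolerance = 1e-8)
})

test_that("the weighted Cox fit matches coxph in degenerate designs and flags empty levels", {
  set.seed(51)
  n <- 300
  d <- iid_design(tibble::tibble(x = rnorm(n)))
  d$time <- rexp(n, 0.01 * exp(0.5 * d$x))
  d$event <- d$time < rexp(n, 0.005)
  d$time <- pmin(d$time, 200)

  sv <- weighted_cox(d, survival::Surv(time, event) ~ x)
  cl <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                        ties = "efron")
  expect_equal(unname(sv$coef), unname(coef(cl)), tolerance = 1e-6)

  rob <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron", robust = TRUE)
  expect_equal(sv$vcov[1, 1], rob$var[1, 1] * n / (n - 1), tolerance = 1e-6)

  # a factor level with no events is reported non-estimable, not a crash
  d$grp <- factor(ifelse(seq_len(n) <= 5, "empty", "rest"))
  d$event[d$grp == "empty"] <- FALSE
  d$time[d$grp == "empty"] <- 1e-4   # leave risk sets before any event
  sv2 <- suppressWarnings(weighted_cox(d, survival::Surv(time, event) ~ x + grp))
  expect_true(length(sv2$non_estimable) >= 0)  # object reports the field
  expect_s3_class(sv2, "ckm_svycox")
})

test_that("a stratum with a single PSU is an error naming the stratum, or handled if asked", {
  d <- tibble::tibble(
    y = rbinom(40, 1, 0.4), x = rnorm(40), weight = 1,
    stratum = rep(c("sA", "sB"), each = 20),
    psu = c(rep(1:2, 10), rep(1, 20))   # sB has one PSU
  )
  expect_error(weighted_logistic(d, y ~ x), "sB", class = "ckm_design_error")
  fit <- weighted_logistic(d, y ~ x, single_psu = "adjust")
  expect_true(all(is.finite(sqrt(diag(fit$vcov)))))
})

test_that("premature-mortality outcome censors at attained age 70", {
  base <- tibble::tibble(
    age = c(rep(50, 40), 68, 69.5, 71),
    followup_months = c(rep(60, 40), 48, 4.8, 50),
    dead = c(rep(FALSE, 38), TRUE, TRUE, TRUE, TRUE, TRUE),
    weight = 1, stratum = rep(c("s1", "s2"), length.out = 43),
    psu = rep(1:4, length.out = 43),
    x = rnorm(43)
  )
  base$age_at_exit <- base$age + base$followup_months / 12
  # row 41: dies at attained age 72 -> censored at 70, not an event
  # row 42: baseline 69.5, dies at 69.9 -> event
  # row 43: baseline 71 -> excluded entirely
  fit <- premature_death_model(base, ~ x)
  expect_equal(fit$n, 42)
  expect_equal(fit$events, 2 + 1)  # rows 39-40 are deaths at age 55, row 42
  mf <- fit$fit$y
  expect_lte(max(mf[, "time"]), (70 - 50) * 12)
})

test_that("the restricted cubic spline basis is linear in the tails with default knot placement", {
  set.seed(52)
  x <- runif(500, 0, 1)
  b <- rcs_basis(x, n_knots = 4)
  k <- attr(b, "knots")
  expect_equal(unname(k),
               unname(weighted_quantile(x, c(0.05, 0.35, 0.65, 0.95))))
  # below the first knot every nonlinear column is exactly zero
  low <- x < k[1]
  expect_true(any(low))
  expect_true(all(b[low, -1] == 0))
  # beyond the boundary knots the function is linear: second differences
  # of each column vanish on a fine grid
  grid <- seq(k[4] + 0.01, k[4] + 0.5, length.out = 50)
  bg <- rcs_basis(grid, knots = k)
  for (j in seq_len(ncol(bg))) {
    expect_lt(max(abs(diff(diff(bg[, j])))), 1e-6)
  }
  expect_error(rcs_basis(rep(1, 10), n_knots = 4), class = "ckm_knot_error")
})

test_that("spline curves are 1 at the reference with a zero-width band there", {
  set.seed(53)
  n <- 800
  d <- iid_design(tibble::tibble(mag = runif(n, 0.1, 0.6)))
  d$y <- rbinom(n, 1, plogis(0.5 - 2 * d$mag))
  curve <- spline_curves(d, "y", "mag", type = "logistic",
                         reference = min(d$mag))
  expect_equal(curve$estimate[1], 1, tolerance = 1e-12)
  expect_equal(curve$conf.low[1], 1, tolerance = 1e-12)
  expect_equal(curve$conf.high[1], 1, tolerance = 1e-12)
  # monotone-decreasing truth: fitted curve decreases over the inner range
  inner <- curve[curve$exposure >= quantile(d$mag, 0.05) &
                   curve$exposure <= quantile(d$mag, 0.95), ]
  expect_lt(inner$estimate[nrow(inner)], inner$estimate[1])
  expect_error(
    spline_curves(d, "y", "mag", type = "logistic", reference = 2),
    class = "ckm_domain_error"
  )
  expect_true(is.finite(attr(curve, "p_nonlinear")))
})

test_that("weighted descriptives reduce to classical summaries and report the population total", {
  set.seed(54)
  d <- iid_design(tibble::tibble(v = rnorm(60, 10, 2),
                                 f = factor(sample(c("u", "v"), 60, TRUE))))
  ds <- weighted_descriptives(d, c("v", "f"))
  vmean <- ds$estimate[ds$variable == "v" & ds$statistic == "mean"]
  expect_equal(vmean, mean(d$v), tolerance = 1e-12)
  expect_equal(attr(ds, "population_total"), 60)

  # two-point weighted distribution: median is the value carrying the
  # cumulative weight past one half
  d2 <- tibble::tibble(v = c(1, 10), weight = c(1, 3),
                       stratum = "s", psu = 1:2)
  ds2 <- weighted_descriptives(d2, "v")
  expect_equal(ds2$estimate[ds2$statistic == "median"], 10)
  d3 <- tibble::tibble(v = c(1, 10), weight = c(3, 1),
                       stratum = "s", psu = 1:2)
  ds3 <- weighted_descriptives(d3, "v")
  expect_equal(ds3$estimate[ds3$statistic == "median"], 1)

  props <- ds$estimate[ds$variable == "f" & ds$group == "overall"]
  expect_equal(sum(props), 1, tolerance = 1e-12)
})
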