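# Restricted (natural) cubic splines, Harrell parameterisation: linear beyond
# the boundary knots, nonlinear columns exactly zero below the first knot.

default_knot_percentiles <- function(n_knots) {
  switch(as.character(n_knots),
    "3" = c(10, 50, 90) / 100,
    "4" = c(5, 35, 65, 95) / 100,
    "5" = c(5, 27.5, 50, 72.5, 95) / 100,
    abort_ckm("n_knots must be 3, 4 or 5", "ckm_domain_error")
  )
}

#' Restricted cubic spline basis
#'
#' Builds the Harrell restricted cubic spline design: the linear term plus
#' `n_knots - 2` nonlinear columns
#' `((x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})) / (t_k - t_1)^2`,
#' which is linear beyond the boundary knots and has all nonlinear columns
#' exactly zero below the first knot. Default knots sit at the 5/35/65/95
#' weighted percentiles (4 knots).
#'
#' @param x Numeric vector.
#' @param n_knots Number of knots (3, 4 or 5); ignored when `knots` is given.
#' @param knots Optional explicit knot locations (strictly increasing).
#' @param weights Optional weights for the percentile knot placement.
#' @return Matrix with columns `x`, `x1`, ... (`n_knots - 1` columns) and
#'   attribute `knots`. Usable directly inside model formulas.
#' @export
rcs_basis <- function(x, n_knots = 4, knots = NULL, weights = NULL) {
  if (is.null(knots)) {
    knots <- weighted_quantile(x, default_knot_percentiles(n_knots),
                               weights, na.rm = TRUE)
  }
  knots <- sort(knots)
  if (any(diff(knots) <= 0)) {
    abort_ckm("spline knots are not distinct (too little variation in x)",
              "ckm_knot_error")
  }
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1]
  scale2 <- (tk - knots[1])^2
  cub <- function(u) pmax(u, 0)^3
  nl <- vapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (cub(x - tj) -
       cub(x - tk1) * (tk - tj) / (tk - tk1) +
       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }, numeric(length(x)))
  out <- cbind(x, matrix(nl, nrow = length(x)))
  colnames(out) <- c("x", paste0("x", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

#' Nonlinear exposure-response curve from a restricted cubic spline fit
#'
#' Fits the Model-4-style design-based regression (logistic for a binary
#' outcome, Cox for a survival outcome) with the exposure entered as a
#' restricted cubic spline, and returns the odds/hazard-ratio curve relative
#' to a reference exposure value, with pointwise delta-method confidence
#' bands. Also reports a Wald test of the nonlinear spline terms.
#'
#' @param data Data frame.
#' @param outcome For `type = "logistic"` the name of the binary outcome
#'   column; for `type = "cox"` a character vector `c(time, event)`.
#' @param exposure Name of the continuous exposure column (phasor magnitude).
#' @param covariates Character vector of adjustment columns.
#' @param type `"logistic"` or `"cox"`.
#' @param n_knots Number of spline knots (default 4, at the 5/35/65/95
#'   weighted percentiles).
#' @param reference Reference exposure value at which the curve equals 1;
#'   default is the weighted median. Must lie inside the observed range.
#' @param grid_n Number of curve evaluation points across the observed range.
#' @inheritParams weighted_logistic
#' @param conf.level Confidence level for the pointwise band.
#' @return A tibble of class `ckm_spline_curve` with columns `exposure`,
#'   `estimate`, `conf.low`, `conf.high`; attributes `reference`, `knots`,
#'   `effect_label`, `p_nonlinear`, and the underlying `fit`.
#' @export
spline_curves <- function(data, outcome, exposure, covariates = character(),
                          type = c("logistic", "cox"), n_knots = 4,
                          reference = NULL, grid_n = 100,
                          weights = "weight", strata = "stratum", psu = "psu",
                          single_psu = "error", conf.level = 0.95) {
  type <- match.arg(type)
  data <- as.data.frame(data)
  x <- data[[exposure]]
  w <- data[[weights]]
  knots <- weighted_quantile(x, default_knot_percentiles(n_knots), w,
                             na.rm = TRUE)
  basis <- rcs_basis(x, knots = knots)
  spline_cols <- paste0(".rcs", seq_len(ncol(basis)))
  for (j in seq_along(spline_cols)) data[[spline_cols[j]]] <- basis[, j]

  rhs <- paste(c(spline_cols, covariates), collapse = " + ")
  if (type == "logistic") {
    f <- as.formula(paste(outcome, "~", rhs))
    fit <- weighted_logistic(data, f, weights, strata, psu, single_psu)
  } else {
    f <- as.formula(paste0("Surv(", outcome[1], ", ", outcome[2], ") ~ ", rhs))
    fit <- weighted_cox(data, f, weights, strata, psu, single_psu)
  }

  rng <- range(x, na.rm = TRUE)
  reference <- reference %||% weighted_quantile(x, 0.5, w, na.rm = TRUE)
  if (reference < rng[1] || reference > rng[2]) {
    abort_ckm("reference value lies outside the observed exposure range",
              "ckm_domain_error")
  }
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  B <- rcs_basis(c(grid, reference), knots = knots)
  C <- sweep(B[seq_len(grid_n), , drop = FALSE], 2L, B[grid_n + 1L, ])

  idx <- match(spline_cols, names(fit$coef))
  beta_s <- fit$coef[idx]
  V_s <- fit$vcov[idx, idx, drop = FALSE]
  eta <- drop(C %*% beta_s)
  se <- sqrt(rowSums((C %*% V_s) * C))
  tcrit <- qt(1 - (1 - conf.level) / 2, max(fit$df_design, 1L))

  nl_idx <- idx[-1L]
  beta_nl <- fit$coef[nl_idx]
  V_nl <- fit$vcov[nl_idx, nl_idx, drop = FALSE]
  wald <- drop(t(beta_nl) %*% solve(V_nl, beta_nl))
  p_nonlin <- pchisq(wald, df = length(beta_nl), lower.tail = FALSE)

  out <- tibble::tibble(
    exposure = grid,
    estimate = exp(eta),
    conf.low = exp(eta - tcrit * se),
    conf.high = exp(eta + tcrit * se)
  )
  class(out) <- c("ckm_spline_curve", class(out))
  attr(out, "reference") <- reference
  attr(out, "knots") <- knots
  attr(out, "effect_label") <- fit$effect_label
  attr(out, "p_nonlinear") <- p_nonlin
  attr(out, "fit") <- fit
  out
}
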