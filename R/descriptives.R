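# Table-1-style weighted descriptive summaries.

svy_mean_se <- function(x, w, domain, strata, psu, single_psu = "adjust") {
  d <- as.numeric(domain) * w
  mu <- sum(d * x, na.rm = TRUE) / sum(d[!is.na(x)])
  infl <- ifelse(is.na(x), 0, d * (x - mu)) / sum(d[!is.na(x)])
  V <- linearized_vcov(matrix(infl, ncol = 1), strata, psu, single_psu)
  c(mean = unname(mu), se = sqrt(V[1, 1]))
}

#' Survey-weighted descriptive summaries
#'
#' Weighted means with linearized standard errors and weighted medians for
#' numeric variables; weighted proportions for factor/logical variables;
#' overall and within groups (survey domains). The weighted population total
#' (sum of sampling weights) is attached as the attribute
#' `population_total` and reported by the `.population` row.
#'
#' @param data Data frame.
#' @param vars Character vector of variable names to summarise.
#' @param by Optional grouping column name (e.g. `"quartile"`).
#' @inheritParams weighted_logistic
#' @return A tidy tibble with columns `variable`, `level`, `group`,
#'   `statistic`, `estimate`, `se`.
#' @export
weighted_descriptives <- function(data, vars, by = NULL, weights = "weight",
                                  strata = "stratum", psu = "psu",
                                  single_psu = "adjust") {
  data <- as.data.frame(data)
  check_design(data, weights, strata, psu, single_psu = "none")
  w <- data[[weights]]
  st <- data[[strata]]
  ps <- data[[psu]]
  groups <- if (is.null(by)) {
    list(overall = rep(TRUE, nrow(data)))
  } else {
    g <- data[[by]]
    c(list(overall = rep(TRUE, nrow(data))),
      setNames(lapply(levels(factor(g)), function(l) !is.na(g) & g == l),
               levels(factor(g))))
  }

  rows <- list()
  for (gname in names(groups)) {
    dom <- groups[[gname]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = ".population", level = NA_character_, group = gname,
      statistic = "weighted_total", estimate = sum(w[dom]), se = NA_real_
    )
    for (v in vars) {
      x <- data[[v]]
      if (is.numeric(x)) {
        ms <- svy_mean_se(x, w, dom, st, ps, single_psu)
        med <- weighted_quantile(x[dom], 0.5, w[dom], na.rm = TRUE)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variable = v, level = NA_character_, group = gname,
          statistic = c("mean", "median"),
          estimate = unname(c(ms["mean"], med)),
          se = unname(c(ms["se"], NA_real_))
        )
      } else {
        f <- factor(x)
        for (l in levels(f)) {
          ind <- as.numeric(!is.na(f) & f == l)
          ms <- svy_mean_se(ind, w, dom, st, ps, single_psu)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            variable = v, level = l, group = gname,
            statistic = "proportion",
            estimate = unname(ms["mean"]), se = unname(ms["se"])
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "population_total") <- sum(w)
  out
}
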