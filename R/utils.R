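# Small numeric helpers shared across modules.

#' Wrap a time offset in hours into the half-open interval (-12, 12]
#'
#' Phase offsets on a 24-hour cycle are reported in the principal interval
#' `(-12, 12]` so that a lag of 13 h and a lead of 11 h are the same offset.
#'
#' @param hours Numeric vector of offsets in hours.
#' @return Numeric vector wrapped into `(-12, 12]`.
#' @export
#' @examples
#' wrap_half_day(c(-12, 13, 25, 12))
wrap_half_day <- function(hours) {
  hours - 24 * ceiling((hours - 12) / 24)
}

# Population (1/N) standard deviation; the phasor machinery standardizes each
# day so that the zero-lag autocorrelation of a signal with itself is exactly 1.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

standardize_pop <- function(x) {
  s <- sd_pop(x)
  if (!is.finite(s) || s < 1e-12) {
    stop("cannot standardize a zero-variance signal", call. = FALSE)
  }
  (x - mean(x)) / s
}

is_standardized <- function(x, tol = 1e-6) {
  abs(mean(x)) <= tol && abs(sd_pop(x) - 1) <= tol
}

#' Weighted quantiles (left-continuous inverse CDF)
#'
#' Returns, for each probability `p`, the smallest observed value whose
#' cumulative weight reaches `p` times the total weight. With unit weights this
#' is the usual type-1 sample quantile. This definition makes quartile
#' cutpoints attainable data values, so ties at a cutpoint can be sent to the
#' lower group deterministically.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @param weights Optional positive weights, recycled to `length(x)`.
#' @param na.rm Drop missing values first?
#' @return Numeric vector, one quantile per element of `probs`.
#' @export
weighted_quantile <- function(x, probs, weights = NULL, na.rm = FALSE) {
  stopifnot(all(probs >= 0 & probs <= 1))
  if (is.null(weights)) weights <- rep(1, length(x))
  weights <- rep_len(weights, length(x))
  if (na.rm) {
    keep <- !is.na(x) & !is.na(weights)
    x <- x[keep]; weights <- weights[keep]
  }
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  cw <- cumsum(weights[ord])
  total <- cw[length(cw)]
  vapply(probs, function(p) {
    if (p == 0) return(xs[1L])
    xs[which(cw >= p * total - 1e-12 * total)[1L]]
  }, numeric(1))
}

# Evaluate a logical rule treating NA as "not fired".
fired <- function(x) !is.na(x) & x

# stop() with a classed condition so callers/tests can discriminate errors.
abort_ckm <- function(msg, class) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
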