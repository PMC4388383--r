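# Distribution fitting from interval summaries. Each Table-style input row
# gives a point estimate and low/high bounds; bounds are read as a central
# 95% interval, so the implied standard deviation is (high - low) / 3.92.
# The divisor is exposed as interval_factor so alternative interpretations
# (e.g. bounds as +-1 sd, factor 2) can be explored without touching code.

#' Fit a beta distribution to a point estimate and 95% bounds
#'
#' Method of moments with mean `m = point` and standard deviation
#' `s = (high - low) / interval_factor`:
#' `alpha = m * (m (1 - m) / s^2 - 1)`, `beta = (1 - m) * (m (1 - m) / s^2 - 1)`.
#'
#' Edge rules: a point estimate of exactly 0 (or 1) leaves the method of
#' moments undefined, so the mean is moved to the middle of its half-interval
#' (`high / 2`, resp. `(1 + low) / 2`) with `s = high / interval_factor`
#' (resp. `(1 - low) / interval_factor`) so the branch stays stochastic. If
#' the implied variance is infeasible (`s^2 >= m (1 - m)`), it is clamped to
#' `0.9 * m (1 - m)` with a warning.
#'
#' @param point,low,high Probabilities with `0 <= low <= point <= high <= 1`
#'   and `low < high`.
#' @param interval_factor Width of the interval in standard deviations
#'   (default 3.92, i.e. a 95% normal interval).
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @examples
#' beta_from_interval(0.5, 0.304, 0.696) # c(alpha = 12, beta = 12)
#' @export
beta_from_interval <- function(point, low, high, interval_factor = 3.92) {
  if (!(low >= 0 && low <= point && point <= high && high <= 1)) {
    stop("beta_from_interval: need 0 <= low <= point <= high <= 1",
         call. = FALSE)
  }
  if (low >= high) stop("beta_from_interval: need low < high", call. = FALSE)
  if (!is.finite(interval_factor) || interval_factor <= 0) {
    stop("interval_factor must be > 0", call. = FALSE)
  }
  m <- point
  s <- (high - low) / interval_factor
  if (m == 0) {
    m <- high / 2
    s <- high / interval_factor
  } else if (m == 1) {
    m <- (1 + low) / 2
    s <- (1 - low) / interval_factor
  }
  vmax <- m * (1 - m)
  if (s^2 >= vmax) {
    warning("beta_from_interval: infeasible variance ", signif(s^2, 4),
            " clamped to 0.9 * m * (1 - m)", call. = FALSE)
    s <- sqrt(0.9 * vmax)
  }
  nu <- vmax / s^2 - 1
  c(alpha = m * nu, beta = (1 - m) * nu)
}

#' Fit a normal distribution to a point estimate and 95% bounds
#'
#' `mu = point`, `sigma = (high - low) / interval_factor`. Used for cost
#' inputs; draws are truncated at zero during sampling.
#'
#' @param point,low,high Costs with `low <= point <= high`, `low < high`,
#'   `point >= 0`.
#' @param interval_factor Width of the interval in standard deviations
#'   (default 3.92).
#' @return Named numeric vector `c(mu = , sigma = )`.
#' @examples
#' normal_from_interval(407, 367, 448) # sigma = 81 / 3.92
#' @export
normal_from_interval <- function(point, low, high, interval_factor = 3.92) {
  if (!(low <= point && point <= high)) {
    stop("normal_from_interval: need low <= point <= high", call. = FALSE)
  }
  if (low >= high) stop("normal_from_interval: need low < high", call. = FALSE)
  if (point < 0) stop("normal_from_interval: need point >= 0", call. = FALSE)
  if (!is.finite(interval_factor) || interval_factor <= 0) {
    stop("interval_factor must be > 0", call. = FALSE)
  }
  c(mu = point, sigma = (high - low) / interval_factor)
}

# Draw n values from the fitted distribution of one uncertain input.
# Degenerate inputs return the point estimate; beta inputs with high > 1 are
# percentages and are fitted/sampled on the /100 scale; normal draws are
# truncated at 0 by resampling.
.sample_input <- function(x, n, interval_factor = 3.92) {
  if (is_fixed_input(x)) return(rep(x$point, n))
  if (x$family == "beta") {
    scale <- if (x$high > 1) 100 else 1
    ab <- beta_from_interval(x$point / scale, x$low / scale, x$high / scale,
                             interval_factor)
    stats::rbeta(n, ab[["alpha"]], ab[["beta"]]) * scale
  } else {
    ms <- normal_from_interval(x$point, x$low, x$high, interval_factor)
    draws <- stats::rnorm(n, ms[["mu"]], ms[["sigma"]])
    while (any(bad <- draws < 0)) {
      draws[bad] <- stats::rnorm(sum(bad), ms[["mu"]], ms[["sigma"]])
    }
    draws
  }
}
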