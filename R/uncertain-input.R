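#' Uncertain model parameter
#'
#' Bundles a point estimate with its low/high uncertainty bounds and the
#' distribution family used when the parameter is resampled in probabilistic
#' sensitivity analysis (PSA). Probabilities are modelled with beta
#' distributions, costs with (zero-truncated) normal distributions, and
#' `"fixed"` inputs are never resampled.
#'
#' HbA1c reductions are stored in percentage points (e.g. `1.48` for a 1.48%
#' reduction). A beta-family input whose upper bound exceeds 1 is interpreted
#' as a percentage and is fitted and sampled on the divided-by-100 scale, so
#' a sampled reduction keeps the mean and spread implied by its bounds while
#' remaining positive.
#'
#' @param point Point estimate: a probability in \[0, 1\], an HbA1c reduction
#'   in percentage points, or a cost in 2014 USD.
#' @param low,high Low and high bounds of the uncertainty interval
#'   (`low <= point <= high`). Bounds are read as a 95% interval when a
#'   sampling distribution is fitted; see [beta_from_interval()].
#' @param family Distribution family used in PSA: `"beta"`, `"normal"`, or
#'   `"fixed"`.
#' @return An object of class `uncertain_input`.
#' @examples
#' uncertain_input(0.1323, 0.1059, 0.1588, "beta")
#' uncertain_input(407, 367, 448, "normal")
#' uncertain_input(0, family = "fixed")
#' @export
uncertain_input <- function(point, low = point, high = point,
                            family = c("beta", "normal", "fixed")) {
  family <- match.arg(family)
  # a collapsed interval has nothing to sample: degrade to fixed
  if (isTRUE(low == high)) family <- "fixed"
  x <- structure(list(point = point, low = low, high = high, family = family),
                 class = "uncertain_input")
  validate_uncertain_input(x)
  x
}

#' Validate an uncertain input
#'
#' Checks the interval ordering (`low <= point <= high`) and the
#' family-specific domain constraints: beta inputs need non-negative bounds
#' (and an upper bound of at most 1, or at most 100 when read as a
#' percentage); normal inputs represent costs and need a non-negative point
#' estimate.
#'
#' @param x An [uncertain_input()].
#' @param where Label used in error messages (e.g. the field name).
#' @return `x`, invisibly; errors describe the violated rule.
#' @export
validate_uncertain_input <- function(x, where = "uncertain_input") {
  if (!inherits(x, "uncertain_input")) {
    stop(where, ": not an uncertain_input", call. = FALSE)
  }
  for (f in c("point", "low", "high")) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(where, ": '", f, "' must be a finite numeric scalar", call. = FALSE)
    }
  }
  if (!(x$family %in% c("beta", "normal", "fixed"))) {
    stop(where, ": unknown distribution family '", x$family, "'", call. = FALSE)
  }
  if (x$low > x$point || x$point > x$high) {
    stop(where, ": interval must satisfy low <= point <= high (got ",
         x$low, ", ", x$point, ", ", x$high, ")", call. = FALSE)
  }
  if (x$family == "beta") {
    if (x$low < 0) stop(where, ": beta inputs require low >= 0", call. = FALSE)
    if (x$high > 100) {
      stop(where, ": beta inputs require high <= 1 (or <= 100 on the ",
           "percentage scale)", call. = FALSE)
    }
  }
  if (x$family == "normal" && x$point < 0) {
    stop(where, ": normal (cost) inputs require point >= 0", call. = FALSE)
  }
  invisible(x)
}

#' Is an input degenerate (never resampled)?
#'
#' An input is fixed either because its family is `"fixed"` or because its
#' interval has collapsed (`low == high`), in which case there is nothing to
#' sample.
#'
#' @param x An [uncertain_input()].
#' @return Logical scalar.
#' @export
is_fixed_input <- function(x) {
  x$family == "fixed" || x$low == x$high
}

#' @export
print.uncertain_input <- function(x, ...) {
  cat(sprintf("<uncertain_input> %g [%g, %g] (%s)\n",
              x$point, x$low, x$high, x$family))
  invisible(x)
}
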