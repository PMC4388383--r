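#' Incremental cost and effect
#'
#' Componentwise differences, intervention minus comparator, of two
#' [evaluate_strategy()] outcomes computed at the same horizon.
#'
#' @param intervention,comparator `strategy_outcome` objects.
#' @return A list with `delta_cost` (USD) and `delta_effect` (percentage
#'   points of HbA1c reduction).
#' @export
incremental_outcomes <- function(intervention, comparator) {
  if (!inherits(intervention, "strategy_outcome") ||
      !inherits(comparator, "strategy_outcome")) {
    stop("incremental_outcomes() expects two strategy_outcome objects",
         call. = FALSE)
  }
  if (intervention$horizon_months != comparator$horizon_months) {
    stop("outcomes were computed at different horizons (",
         intervention$horizon_months, " vs ", comparator$horizon_months,
         " months)", call. = FALSE)
  }
  list(delta_cost = intervention$total_cost - comparator$total_cost,
       delta_effect = intervention$hba1c_reduction - comparator$hba1c_reduction)
}

#' ICER with dominance classification
#'
#' Classifies an incremental (cost, effect) pair on the cost-effectiveness
#' plane and computes the incremental cost-effectiveness ratio where it is
#' meaningful:
#'
#' * `NE` (costlier, more effective) — `icer = delta_cost / delta_effect`;
#' * `SE` (no costlier, no less effective, not identical) — the intervention
#'   dominates; the ICER is undefined;
#' * `NW` — the intervention is dominated; the ICER is undefined (this
#'   includes `delta_effect == 0` with `delta_cost > 0`);
#' * `SW` (cheaper, less effective) — the ratio is reported numerically but
#'   flagged, because a *lower* ratio favours the intervention there;
#' * both deltas zero — `"equivalent"`, ICER undefined.
#'
#' @param delta_cost,delta_effect Finite incremental cost (USD) and effect
#'   (percentage points), intervention minus comparator.
#' @return An object of class `incremental_result` with fields `delta_cost`,
#'   `delta_effect`, `icer` (`NA` when undefined), `quadrant`, and `status`
#'   (`"ratio"`, `"dominant"`, `"dominated"`, `"sw_ratio"`, `"equivalent"`).
#' @examples
#' icer_with_dominance(891, 0.1867)  # NE, icer about 4773
#' icer_with_dominance(-10, 0.1)     # dominant
#' @export
icer_with_dominance <- function(delta_cost, delta_effect) {
  if (!is.finite(delta_cost) || !is.finite(delta_effect)) {
    stop("delta_cost and delta_effect must be finite", call. = FALSE)
  }
  if (delta_cost == 0 && delta_effect == 0) {
    quadrant <- "equivalent"; status <- "equivalent"; icer <- NA_real_
  } else if (delta_effect > 0 && delta_cost > 0) {
    quadrant <- "NE"; status <- "ratio"; icer <- delta_cost / delta_effect
  } else if (delta_effect < 0 && delta_cost < 0) {
    quadrant <- "SW"; status <- "sw_ratio"; icer <- delta_cost / delta_effect
  } else if (delta_effect >= 0 && delta_cost <= 0) {
    quadrant <- "SE"; status <- "dominant"; icer <- NA_real_
  } else {
    quadrant <- "NW"; status <- "dominated"; icer <- NA_real_
  }
  structure(list(delta_cost = delta_cost, delta_effect = delta_effect,
                 icer = icer, quadrant = quadrant, status = status),
            class = "incremental_result")
}

#' Net monetary benefit
#'
#' `NMB(lambda) = lambda * delta_effect - delta_cost` for willingness to pay
#' `lambda` in USD per 1% HbA1c reduction. Positive NMB means the
#' intervention is the cost-effective choice at that threshold.
#'
#' @param wtp Willingness to pay, >= 0 (vectorised).
#' @param delta_effect Incremental effect in percentage points.
#' @param delta_cost Incremental cost in USD.
#' @return NMB in USD, one value per `wtp`.
#' @export
net_monetary_benefit <- function(wtp, delta_effect, delta_cost) {
  if (any(!is.finite(wtp) | wtp < 0)) {
    stop("wtp must be >= 0", call. = FALSE)
  }
  wtp * delta_effect - delta_cost
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> dCost $%.2f, dEffect %.4f%% (%s)\n",
              x$delta_cost, x$delta_effect, x$quadrant))
  if (x$status == "ratio") {
    cat(sprintf("  ICER: $%s per 1%% HbA1c reduction\n",
                format(round(x$icer))))
  } else if (x$status == "sw_ratio") {
    cat(sprintf("  SW-quadrant ratio: $%s (lower favours the intervention)\n",
                format(round(x$icer))))
  } else {
    cat(sprintf("  intervention is %s; ICER undefined\n", x$status))
  }
  invisible(x)
}
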