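# Closed-form evaluation of the decision tree. The cohort splits
# sequentially: a fraction p_disc_early stops before week 4 (1 month of drug
# cost, no HbA1c benefit); of the remainder, p_disc_late stops after week 4
# (3 months of drug cost, no benefit); completers accrue drug cost for the
# whole horizon and the full-course HbA1c reduction. Adverse-event cost is an
# independent branch applied to the whole cohort: a gastrointestinal episode
# (probability p_any_teae * p_gi_given_teae) costs gi_event_cost.
# Discontinuation itself carries no extra cost.

# Vectorised core shared by evaluate_strategy() (scalars) and run_psa()
# (one value per Monte Carlo draw), so the conservation identity
# total = drug + ae + disc holds by construction on both paths.
.cohort_eval <- function(monthly_cost, p_disc_early, p_disc_late,
                         p_any_teae, p_gi_given_teae, gi_event_cost,
                         full_reduction, horizon_months) {
  retention_early <- 1 - p_disc_early
  retention_full <- retention_early * (1 - p_disc_late)
  drug <- p_disc_early * monthly_cost +
    retention_early * p_disc_late * 3 * monthly_cost +
    retention_full * horizon_months * monthly_cost
  ae <- p_any_teae * p_gi_given_teae * gi_event_cost
  disc <- rep(0, length(drug))
  list(retention_early = retention_early,
       retention_full = retention_full,
       drug_cost = drug,
       ae_cost = ae,
       disc_cost = disc,
       total_cost = drug + ae + disc,
       hba1c_reduction = retention_full * full_reduction)
}

.check_prob <- function(x, nm) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop(nm, " must be a probability in [0, 1]", call. = FALSE)
  }
}

.check_horizon <- function(horizon_months) {
  if (length(horizon_months) != 1L || !(horizon_months %in% c(6, 12))) {
    stop("horizon_months must be 6 or 12", call. = FALSE)
  }
}

#' Retention fractions of the discontinuation tree
#'
#' The tree branches sequentially: `retention_early = 1 - p_disc_early` is
#' the fraction still on treatment after week 4, and
#' `retention_full = (1 - p_disc_early) * (1 - p_disc_late)` the fraction
#' completing the full course (`p_disc_late` is conditional on surviving
#' week 4).
#'
#' @param p_disc_early,p_disc_late Probabilities in \[0, 1\] (vectorised).
#' @return A list with components `retention_early` and `retention_full`.
#' @examples
#' retention_fractions(0, 0.1323)       # 1, 0.8677
#' retention_fractions(0.0333, 0.0978)  # 0.9667, 0.8721...
#' @export
retention_fractions <- function(p_disc_early, p_disc_late) {
  .check_prob(p_disc_early, "p_disc_early")
  .check_prob(p_disc_late, "p_disc_late")
  re <- 1 - p_disc_early
  list(retention_early = re, retention_full = re * (1 - p_disc_late))
}

#' Expected per-patient drug cost
#'
#' Early discontinuers are charged 1 month of drug cost (28 days of
#' treatment), late discontinuers 3 months (12 weeks), completers the full
#' horizon:
#' `p_disc_early * m + (1 - p_disc_early) * p_disc_late * 3m +
#'  retention_full * horizon * m`.
#'
#' @param monthly_total_cost USD per month (drug plus supplies), >= 0.
#' @param p_disc_early,p_disc_late Probabilities in \[0, 1\].
#' @param horizon_months 6 or 12.
#' @return Expected USD per patient.
#' @examples
#' expected_drug_cost(407, 0, 0.1323, 6)
#' @export
expected_drug_cost <- function(monthly_total_cost, p_disc_early, p_disc_late,
                               horizon_months) {
  if (any(!is.finite(monthly_total_cost) | monthly_total_cost < 0)) {
    stop("monthly_total_cost must be >= 0", call. = FALSE)
  }
  .check_prob(p_disc_early, "p_disc_early")
  .check_prob(p_disc_late, "p_disc_late")
  .check_horizon(horizon_months)
  re <- 1 - p_disc_early
  rf <- re * (1 - p_disc_late)
  p_disc_early * monthly_total_cost +
    re * p_disc_late * 3 * monthly_total_cost +
    rf * horizon_months * monthly_total_cost
}

#' Expected per-patient adverse-event cost
#'
#' A gastrointestinal episode costs `gi_event_cost` and occurs with
#' probability `p_any_teae * p_gi_given_teae`, applied to the whole cohort.
#'
#' @param p_any_teae,p_gi_given_teae Probabilities in \[0, 1\].
#' @param gi_event_cost USD per episode, >= 0.
#' @return Expected USD per patient.
#' @examples
#' expected_ae_cost(0.6139, 0.3993, 1113) # 272.83, i.e. $273
#' @export
expected_ae_cost <- function(p_any_teae, p_gi_given_teae, gi_event_cost) {
  .check_prob(p_any_teae, "p_any_teae")
  .check_prob(p_gi_given_teae, "p_gi_given_teae")
  if (any(!is.finite(gi_event_cost) | gi_event_cost < 0)) {
    stop("gi_event_cost must be >= 0", call. = FALSE)
  }
  p_any_teae * p_gi_given_teae * gi_event_cost
}

#' Expected per-patient HbA1c reduction
#'
#' Discontinuers return to their baseline HbA1c, so only completers
#' contribute: `retention_full * full_course_reduction`.
#'
#' @param full_course_reduction Percentage points, >= 0.
#' @param retention_full Fraction in \[0, 1\].
#' @return Expected HbA1c reduction in percentage points.
#' @export
expected_effect <- function(full_course_reduction, retention_full) {
  if (any(!is.finite(full_course_reduction) | full_course_reduction < 0)) {
    stop("full_course_reduction must be >= 0", call. = FALSE)
  }
  .check_prob(retention_full, "retention_full")
  retention_full * full_course_reduction
}

#' Evaluate one strategy of the decision tree
#'
#' Composes the cohort expectations at point estimates: drug cost from the
#' discontinuation strata (using `monthly_drug_cost + monthly_supply_cost`
#' per month), adverse-event cost, a structural 0 discontinuation cost, and
#' the retention-scaled HbA1c reduction.
#'
#' @param strategy A [strategy_inputs()] object.
#' @param shared A [shared_inputs()] object.
#' @param horizon_months Optional override of `shared$horizon_months`.
#' @return An object of class `strategy_outcome` with fields `name`,
#'   `horizon_months`, `retention_early`, `retention_full`, `drug_cost`,
#'   `ae_cost`, `disc_cost`, `total_cost`, `hba1c_reduction`.
#' @examples
#' scn <- builtin_scenario("duration6")
#' evaluate_strategy(scn$comparator, scn$shared)
#' @export
evaluate_strategy <- function(strategy, shared, horizon_months = NULL) {
  validate_strategy_inputs(strategy, strategy$name)
  validate_shared_inputs(shared)
  h <- if (is.null(horizon_months)) shared$horizon_months else horizon_months
  .check_horizon(h)
  out <- .cohort_eval(
    monthly_cost    = strategy$monthly_drug_cost$point +
      strategy$monthly_supply_cost$point,
    p_disc_early    = strategy$p_disc_early$point,
    p_disc_late     = strategy$p_disc_late$point,
    p_any_teae      = strategy$p_any_teae$point,
    p_gi_given_teae = strategy$p_gi_given_teae$point,
    gi_event_cost   = shared$gi_event_cost$point,
    full_reduction  = strategy$hba1c_reduction$point,
    horizon_months  = h)
  structure(c(list(name = strategy$name, horizon_months = h), out),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s, %d-month horizon\n",
              x$name, x$horizon_months))
  cat(sprintf("  drug cost        $%s\n", format(round(x$drug_cost))))
  cat(sprintf("  adverse events   $%s\n", format(round(x$ae_cost))))
  cat(sprintf("  discontinuation  $%s\n", format(round(x$disc_cost))))
  cat(sprintf("  total cost       $%s\n", format(round(x$total_cost))))
  cat(sprintf("  HbA1c reduction  -%.2f%%\n", x$hba1c_reduction))
  invisible(x)
}
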