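# Field registry for the per-strategy inputs. The "kind" drives validation
# (probabilities bounded in [0,1], costs non-negative, effects positive) and
# the order fixes the parameter-sampling sequence in run_psa(), so it must
# not be reordered.
.STRATEGY_FIELDS <- c(
  hba1c_reduction     = "effect",
  p_disc_early        = "prob",
  p_disc_late         = "prob",
  monthly_drug_cost   = "cost",
  monthly_supply_cost = "cost",
  p_any_teae          = "prob",
  p_gi_given_teae     = "prob"
)

#' Per-strategy model inputs
#'
#' Collects every strategy-level parameter of the decision tree: the
#' full-course HbA1c reduction, the two sequential discontinuation
#' probabilities (before week 4, and after week 4 conditional on remaining),
#' monthly drug and supply (needle) acquisition costs, and the adverse-event
#' chain (probability of at least one treatment-emergent adverse event, and
#' probability of a gastrointestinal event given one).
#'
#' @param name Strategy name (e.g. `"liraglutide"`).
#' @param hba1c_reduction [uncertain_input()]; full-course HbA1c reduction in
#'   percentage points, stored as a positive magnitude.
#' @param p_disc_early [uncertain_input()]; probability of discontinuing
#'   before week 4.
#' @param p_disc_late [uncertain_input()]; probability of discontinuing after
#'   week 4, conditional on not discontinuing early.
#' @param monthly_drug_cost [uncertain_input()]; USD per month.
#' @param monthly_supply_cost [uncertain_input()]; USD per month for
#'   consumables (needles); defaults to a fixed 0.
#' @param p_any_teae [uncertain_input()]; probability of >= 1
#'   treatment-emergent adverse event.
#' @param p_gi_given_teae [uncertain_input()]; probability of a
#'   gastrointestinal event given >= 1 TEAE.
#' @return An object of class `strategy_inputs`.
#' @export
strategy_inputs <- function(name, hba1c_reduction, p_disc_early, p_disc_late,
                            monthly_drug_cost,
                            monthly_supply_cost = uncertain_input(0, family = "fixed"),
                            p_any_teae, p_gi_given_teae) {
  x <- structure(
    list(name = name,
         hba1c_reduction = hba1c_reduction,
         p_disc_early = p_disc_early,
         p_disc_late = p_disc_late,
         monthly_drug_cost = monthly_drug_cost,
         monthly_supply_cost = monthly_supply_cost,
         p_any_teae = p_any_teae,
         p_gi_given_teae = p_gi_given_teae),
    class = "strategy_inputs")
  validate_strategy_inputs(x)
  x
}

#' Validate per-strategy inputs
#'
#' @param x A [strategy_inputs()] object.
#' @param where Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_strategy_inputs <- function(x, where = "strategy") {
  if (!inherits(x, "strategy_inputs")) {
    stop(where, ": not a strategy_inputs object", call. = FALSE)
  }
  if (!is.character(x$name) || length(x$name) != 1L || !nzchar(x$name)) {
    stop(where, ": 'name' must be a non-empty string", call. = FALSE)
  }
  for (f in names(.STRATEGY_FIELDS)) {
    lab <- paste0(where, ".", f)
    u <- x[[f]]
    validate_uncertain_input(u, lab)
    kind <- .STRATEGY_FIELDS[[f]]
    if (kind == "prob") {
      if (u$low < 0 || u$high > 1) {
        stop(lab, ": probability bounds must lie in [0, 1]", call. = FALSE)
      }
    } else if (kind == "cost") {
      if (u$low < 0) stop(lab, ": costs must be >= 0", call. = FALSE)
    } else { # effect
      if (u$point <= 0) {
        stop(lab, ": HbA1c reduction must be a positive magnitude",
             call. = FALSE)
      }
      if (u$low < 0) stop(lab, ": effect bounds must be >= 0", call. = FALSE)
    }
  }
  invisible(x)
}

#' Inputs shared by both strategies
#'
#' @param gi_event_cost [uncertain_input()]; 2014 USD per gastrointestinal
#'   adverse-event episode.
#' @param horizon_months Analysis horizon; 6 or 12 months.
#' @param wtp_grid Strictly increasing non-negative willingness-to-pay grid
#'   in USD per 1% HbA1c reduction, used for the acceptability curve.
#' @return An object of class `shared_inputs`.
#' @export
shared_inputs <- function(gi_event_cost, horizon_months = 6L,
                          wtp_grid = seq(0, 5000, by = 100)) {
  x <- structure(
    list(gi_event_cost = gi_event_cost,
         horizon_months = as.integer(horizon_months),
         wtp_grid = as.numeric(wtp_grid)),
    class = "shared_inputs")
  validate_shared_inputs(x)
  x
}

#' Validate shared inputs
#'
#' @param x A [shared_inputs()] object.
#' @param where Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_shared_inputs <- function(x, where = "shared") {
  if (!inherits(x, "shared_inputs")) {
    stop(where, ": not a shared_inputs object", call. = FALSE)
  }
  validate_uncertain_input(x$gi_event_cost, paste0(where, ".gi_event_cost"))
  if (x$gi_event_cost$low < 0) {
    stop(where, ".gi_event_cost: costs must be >= 0", call. = FALSE)
  }
  if (!(x$horizon_months %in% c(6L, 12L))) {
    stop(where, ".horizon_months: must be 6 or 12", call. = FALSE)
  }
  g <- x$wtp_grid
  if (length(g) < 1L || any(!is.finite(g))) {
    stop(where, ".wtp_grid: must be a non-empty finite numeric vector",
         call. = FALSE)
  }
  if (any(g < 0)) stop(where, ".wtp_grid: values must be >= 0", call. = FALSE)
  if (length(g) > 1L && any(diff(g) <= 0)) {
    stop(where, ".wtp_grid: must be strictly increasing", call. = FALSE)
  }
  invisible(x)
}

#' A two-strategy cost-effectiveness scenario
#'
#' A scenario pairs the intervention (liraglutide role) with the comparator
#' (exenatide role) and the shared inputs, under a label naming the clinical
#' data source of the effectiveness inputs: the DURATION-6 head-to-head
#' trial, a network meta-analysis, or `"custom"`.
#'
#' @param intervention,comparator [strategy_inputs()] objects.
#' @param shared A [shared_inputs()] object.
#' @param label `"duration6"`, `"meta_analysis"`, or `"custom"`.
#' @return An object of class `ce_scenario`.
#' @seealso [builtin_scenario()] for the two bundled parameter sets,
#'   [load_scenario()] / [write_scenario()] for file I/O.
#' @export
scenario <- function(intervention, comparator, shared,
                     label = c("custom", "duration6", "meta_analysis")) {
  label <- match.arg(label)
  x <- structure(
    list(label = label, intervention = intervention,
         comparator = comparator, shared = shared),
    class = "ce_scenario")
  validate_scenario(x)
  x
}

#' Validate a scenario
#'
#' @param x A [scenario()] object.
#' @return `x`, invisibly; errors name the offending field and rule.
#' @export
validate_scenario <- function(x) {
  if (!inherits(x, "ce_scenario")) stop("not a ce_scenario", call. = FALSE)
  if (!(x$label %in% c("duration6", "meta_analysis", "custom"))) {
    stop("label: must be one of duration6, meta_analysis, custom",
         call. = FALSE)
  }
  validate_strategy_inputs(x$intervention, "intervention")
  validate_strategy_inputs(x$comparator, "comparator")
  validate_shared_inputs(x$shared, "shared")
  invisible(x)
}

# Replace the point estimate of one input in a scenario; used by the one-way
# sweep. role is "intervention", "comparator" or "shared"; field a name in
# .STRATEGY_FIELDS or "gi_event_cost".
.set_point <- function(scn, role, field, value) {
  scn[[role]][[field]]$point <- value
  scn
}

# Enumerate every uncertain input of a scenario as (role, field) pairs.
.scenario_inputs <- function(scn) {
  rows <- list()
  for (role in c("intervention", "comparator")) {
    for (f in names(.STRATEGY_FIELDS)) {
      rows[[length(rows) + 1L]] <- list(role = role, field = f)
    }
  }
  rows[[length(rows) + 1L]] <- list(role = "shared", field = "gi_event_cost")
  rows
}

#' @export
print.ce_scenario <- function(x, ...) {
  cat(sprintf("<ce_scenario> label=%s horizon=%d months\n",
              x$label, x$shared$horizon_months))
  fmt <- function(u) sprintf("%g [%g, %g] %s", u$point, u$low, u$high, u$family)
  for (role in c("intervention", "comparator")) {
    s <- x[[role]]
    cat(sprintf("  %s (%s):\n", role, s$name))
    for (f in names(.STRATEGY_FIELDS)) {
      cat(sprintf("    %-20s %s\n", f, fmt(s[[f]])))
    }
  }
  cat(sprintf("  shared.gi_event_cost   %s\n", fmt(x$shared$gi_event_cost)))
  cat(sprintf("  wtp_grid: %g .. %g (%d points)\n",
              min(x$shared$wtp_grid), max(x$shared$wtp_grid),
              length(x$shared$wtp_grid)))
  invisible(x)
}
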