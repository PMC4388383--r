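# One-way (deterministic) sensitivity analysis: each uncertain input is set
# to its low and then its high bound with every other input at its point
# estimate, the full model is re-evaluated, and inputs are ranked by the
# width of the induced outcome range (tornado ordering).

.incremental_value <- function(scn, outcome) {
  oi <- evaluate_strategy(scn$intervention, scn$shared)
  oc <- evaluate_strategy(scn$comparator, scn$shared)
  inc <- incremental_outcomes(oi, oc)
  switch(outcome,
         delta_cost = inc$delta_cost,
         delta_effect = inc$delta_effect,
         icer = if (inc$delta_effect == 0) NA_real_ else
           inc$delta_cost / inc$delta_effect)
}

#' One-way sensitivity sweep (tornado analysis)
#'
#' Perturbs each uncertain input of the scenario to its low and high bound
#' in turn, holding all others at their point estimates, and records the
#' resulting incremental outcome. Entries are sorted by the width of the
#' induced range, descending, which is the ordering of a tornado diagram.
#' Degenerate inputs (collapsed intervals) have width 0 and rank last.
#'
#' @param scenario A validated [scenario()].
#' @param outcome Which incremental outcome to sweep: `"delta_cost"` (USD),
#'   `"delta_effect"` (percentage points), or `"icer"` (the raw ratio; `NA`
#'   where the incremental effect vanishes).
#' @param top_k Optional: keep only the `top_k` widest entries (tornado
#'   diagrams conventionally display the 10 most influential inputs).
#' @return A data frame of class `tornado` with columns `input` (e.g.
#'   `"comparator.monthly_drug_cost"`), `strategy`, `parameter`,
#'   `outcome_at_low`, `outcome_at_high`, `width`; the base-case outcome is
#'   attached as attribute `"base_value"`.
#' @examples
#' tw <- one_way_sweep(builtin_scenario("duration6"), "delta_cost")
#' head(tw, 3)
#' @export
one_way_sweep <- function(scenario,
                          outcome = c("delta_cost", "delta_effect", "icer"),
                          top_k = NULL) {
  outcome <- match.arg(outcome)
  validate_scenario(scenario)
  base <- .incremental_value(scenario, outcome)
  specs <- .scenario_inputs(scenario)
  rows <- lapply(specs, function(sp) {
    u <- scenario[[sp$role]][[sp$field]]
    at <- function(v) {
      .incremental_value(.set_point(scenario, sp$role, sp$field, v), outcome)
    }
    lo <- at(u$low)
    hi <- at(u$high)
    data.frame(
      input = paste(sp$role, sp$field, sep = "."),
      strategy = if (sp$role == "shared") "shared" else scenario[[sp$role]]$name,
      parameter = sp$field,
      outcome_at_low = lo,
      outcome_at_high = hi,
      width = abs(hi - lo))
  })
  tw <- do.call(rbind, rows)
  tw <- tw[order(-tw$width, tw$input), , drop = FALSE]
  if (!is.null(top_k)) tw <- utils::head(tw, top_k)
  rownames(tw) <- NULL
  attr(tw, "base_value") <- base
  attr(tw, "outcome") <- outcome
  class(tw) <- c("tornado", "data.frame")
  tw
}
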