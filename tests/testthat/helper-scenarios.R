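# Shared fixtures built in code.

# A scenario whose every interval is collapsed to the point estimate, so the
# PSA has zero parameter uncertainty and every draw equals the base case.
degenerate_scenario <- function(base = builtin_scenario("duration6")) {
  for (role in c("intervention", "comparator")) {
    for (f in names(glp1ce:::.STRATEGY_FIELDS)) {
      p <- base[[role]][[f]]$point
      base[[role]][[f]] <- uncertain_input(p, p, p, "fixed")
    }
  }
  p <- base$shared$gi_event_cost$point
  base$shared$gi_event_cost <- uncertain_input(p, p, p, "fixed")
  validate_scenario(base)
  base
}

# Strip the four effectiveness fields so the two built-in scenarios can be
# compared on everything else.
drop_effectiveness <- function(scn) {
  scn$label <- "custom"
  scn$intervention$hba1c_reduction <- NULL
  scn$comparator$hba1c_reduction <- NULL
  scn
}
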