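#' Built-in scenarios
#'
#' Returns one of the two bundled parameter sets for the liraglutide QD
#' 1.8 mg vs exenatide QW 2 mg comparison. The two labels share every input
#' except the full-course HbA1c reductions:
#'
#' * `"duration6"` — effectiveness from the DURATION-6 head-to-head trial
#'   (liraglutide 1.48%, exenatide 1.28%);
#' * `"meta_analysis"` — effectiveness from a 22-study network meta-analysis
#'   (liraglutide 1.18%, exenatide 1.15%).
#'
#' All remaining inputs (discontinuation probabilities, 2014 wholesale
#' acquisition costs, adverse-event probabilities, and the $1,113
#' gastrointestinal episode cost) are identical across the two labels.
#' The liraglutide strategy carries a fixed $9/month needle cost on top of
#' the $536 monthly pack price; the exenatide pen needs no separate needles,
#' so its supply cost is a fixed 0.
#'
#' @param label `"duration6"` or `"meta_analysis"`.
#' @return A validated [scenario()].
#' @examples
#' scn <- builtin_scenario("duration6")
#' scn$comparator$p_disc_late$point # 0.1323
#' @export
builtin_scenario <- function(label = c("duration6", "meta_analysis")) {
  label <- match.arg(label)
  eff <- switch(label,
    duration6 = list(
      intervention = uncertain_input(1.48, 1.38, 1.58, "beta"),
      comparator   = uncertain_input(1.28, 1.18, 1.38, "beta")),
    meta_analysis = list(
      intervention = uncertain_input(1.18, 1.04, 1.32, "beta"),
      comparator   = uncertain_input(1.15, 1.00, 1.31, "beta")))

  intervention <- strategy_inputs(
    name                = "liraglutide",
    hba1c_reduction     = eff$intervention,
    p_disc_early        = uncertain_input(0.0333, 0.0266, 0.0400, "beta"),
    p_disc_late         = uncertain_input(0.0978, 0.0782, 0.1174, "beta"),
    monthly_drug_cost   = uncertain_input(536, 482, 589, "normal"),
    monthly_supply_cost = uncertain_input(9, 8, 10, "normal"),
    p_any_teae          = uncertain_input(0.6489, 0.5191, 0.7787, "beta"),
    p_gi_given_teae     = uncertain_input(0.547, 0.4378, 0.6566, "beta"))

  comparator <- strategy_inputs(
    name                = "exenatide",
    hba1c_reduction     = eff$comparator,
    p_disc_early        = uncertain_input(0, 0, 0.01, "beta"),
    p_disc_late         = uncertain_input(0.1323, 0.1059, 0.1588, "beta"),
    monthly_drug_cost   = uncertain_input(407, 367, 448, "normal"),
    monthly_supply_cost = uncertain_input(0, family = "fixed"),
    p_any_teae          = uncertain_input(0.6139, 0.4911, 0.7367, "beta"),
    p_gi_given_teae     = uncertain_input(0.3993, 0.3194, 0.4792, "beta"))

  shared <- shared_inputs(
    gi_event_cost  = uncertain_input(1113, 890, 1335, "normal"),
    horizon_months = 6L,
    wtp_grid       = seq(0, 5000, by = 100))

  scenario(intervention, comparator, shared, label = label)
}
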