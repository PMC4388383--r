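# Synthetic scenarios and a patient-level micro-simulation oracle. The
# oracle realises the same tree per patient (sequential discontinuation,
# independent adverse-event branch) so its sample means provide an
# independent check of the closed-form cohort expectations.

#' Generate a random valid scenario
#'
#' Draws a two-strategy scenario with realistic, self-consistent inputs for
#' property-based testing: probabilities from (0.01, 0.6), full-course
#' HbA1c reductions from (0.2, 2.5) percentage points, monthly costs from
#' (50, 1500) USD, and a gastrointestinal episode cost from (200, 3000) USD.
#' Bounds are set to 0.8x / 1.2x the point estimate, clamped to the field's
#' domain; probabilities and effects are beta-family, costs normal. The
#' horizon is 6 or 12 months with equal probability. Deterministic in
#' `seed`; the caller's RNG state is restored on exit.
#'
#' @param seed Integer seed.
#' @return A validated [scenario()] with label `"custom"`.
#' @export
random_scenario <- function(seed) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  rin <- function(point, kind) {
    low <- 0.8 * point
    high <- 1.2 * point
    if (kind == "prob") {
      high <- min(high, 1)
      uncertain_input(point, low, high, "beta")
    } else if (kind == "effect") {
      uncertain_input(point, low, high, "beta")
    } else {
      uncertain_input(point, low, high, "normal")
    }
  }
  rand_strategy <- function(name) {
    strategy_inputs(
      name                = name,
      hba1c_reduction     = rin(stats::runif(1, 0.2, 2.5), "effect"),
      p_disc_early        = rin(stats::runif(1, 0.01, 0.6), "prob"),
      p_disc_late         = rin(stats::runif(1, 0.01, 0.6), "prob"),
      monthly_drug_cost   = rin(stats::runif(1, 50, 1500), "cost"),
      monthly_supply_cost = rin(stats::runif(1, 50, 1500), "cost"),
      p_any_teae          = rin(stats::runif(1, 0.01, 0.6), "prob"),
      p_gi_given_teae     = rin(stats::runif(1, 0.01, 0.6), "prob"))
  }
  intervention <- rand_strategy("synthetic_intervention")
  comparator <- rand_strategy("synthetic_comparator")
  shared <- shared_inputs(
    gi_event_cost  = rin(stats::runif(1, 200, 3000), "cost"),
    horizon_months = sample(c(6L, 12L), 1L),
    wtp_grid       = seq(0, 5000, by = 100))
  scenario(intervention, comparator, shared, label = "custom")
}

#' Patient-level micro-simulation oracle
#'
#' Realises the decision tree per patient at the scenario's point-estimate
#' probabilities: each patient draws an early-discontinuation indicator,
#' then (if still on treatment) a late-discontinuation indicator, and an
#' independent adverse-event chain (any TEAE, then a gastrointestinal event
#' given a TEAE). Early discontinuers accrue 1 month of drug cost, late
#' discontinuers 3 months, completers the full horizon; a gastrointestinal
#' event costs the shared episode cost; only completers realise the
#' full-course HbA1c reduction. Sample means and their standard errors
#' estimate the same quantities that [evaluate_strategy()] computes in
#' closed form, making this an independent validation oracle.
#'
#' @param scenario A validated [scenario()].
#' @param strategy_role `"intervention"` or `"comparator"`.
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param horizon_months Optional override of the scenario horizon.
#' @return An object of class `micro_sim`: `n_patients`, `mean` and `se`
#'   (named numeric vectors over `retention_early`, `retention_full`,
#'   `drug_cost`, `ae_cost`, `disc_cost`, `total_cost`, `hba1c_reduction`).
#' @export
simulate_patients <- function(scenario,
                              strategy_role = c("intervention", "comparator"),
                              n_patients, seed, horizon_months = NULL) {
  strategy_role <- match.arg(strategy_role)
  validate_scenario(scenario)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  n <- as.integer(n_patients)
  s <- scenario[[strategy_role]]
  h <- if (is.null(horizon_months)) scenario$shared$horizon_months else
    horizon_months
  .check_horizon(h)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)

  disc_early <- stats::rbinom(n, 1L, s$p_disc_early$point)
  disc_late <- (1L - disc_early) * stats::rbinom(n, 1L, s$p_disc_late$point)
  had_teae <- stats::rbinom(n, 1L, s$p_any_teae$point)
  had_gi <- had_teae * stats::rbinom(n, 1L, s$p_gi_given_teae$point)

  monthly <- s$monthly_drug_cost$point + s$monthly_supply_cost$point
  months <- ifelse(disc_early == 1L, 1, ifelse(disc_late == 1L, 3, h))
  drug_cost <- months * monthly
  ae_cost <- had_gi * scenario$shared$gi_event_cost$point
  disc_cost <- rep(0, n)
  total_cost <- drug_cost + ae_cost + disc_cost
  completer <- disc_early == 0L & disc_late == 0L
  effect <- ifelse(completer, s$hba1c_reduction$point, 0)

  fields <- list(retention_early = as.numeric(disc_early == 0L),
                 retention_full = as.numeric(completer),
                 drug_cost = drug_cost,
                 ae_cost = ae_cost,
                 disc_cost = disc_cost,
                 total_cost = total_cost,
                 hba1c_reduction = effect)
  means <- vapply(fields, mean, 0)
  ses <- vapply(fields, function(v) stats::sd(v) / sqrt(n), 0)
  structure(list(strategy = s$name, strategy_role = strategy_role,
                 horizon_months = h, n_patients = n, seed = as.integer(seed),
                 mean = means, se = ses),
            class = "micro_sim")
}

#' @export
print.micro_sim <- function(x, ...) {
  cat(sprintf("<micro_sim> %s, %d patients, %d-month horizon\n",
              x$strategy, x$n_patients, x$horizon_months))
  for (f in names(x$mean)) {
    cat(sprintf("  %-16s %12.4f (se %.4f)\n", f, x$mean[[f]], x$se[[f]]))
  }
  invisible(x)
}
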