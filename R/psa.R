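#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of input uncertainty through the decision tree.
#' Every non-fixed input is drawn independently from its fitted distribution
#' (beta for probabilities and HbA1c reductions, zero-truncated normal for
#' costs; see [beta_from_interval()] and [normal_from_interval()]); the
#' shared gastrointestinal episode cost is drawn once per run and used in
#' both arms. Both strategies are then evaluated in closed form at the
#' scenario horizon and the incremental (cost, effect) pair recorded.
#'
#' Sampling is deterministic for a fixed seed: inputs are drawn in a fixed
#' order (intervention fields, comparator fields, then the shared cost, each
#' in the registry order of [strategy_inputs()]). The caller's RNG state is
#' restored on exit.
#'
#' @param scenario A validated [scenario()].
#' @param n_runs Number of Monte Carlo runs (default 5000).
#' @param seed Integer seed stored in the result.
#' @param interval_factor Interval interpretation passed to the distribution
#'   fits (default 3.92: bounds read as a 95% interval).
#' @return An object of class `psa_result`: `n_runs`, `seed`,
#'   `interval_factor`, `horizon_months`, `draws` (data frame `run`,
#'   `delta_cost`, `delta_effect`), `intervention_draws` /
#'   `comparator_draws` (per-arm outcome components per run),
#'   `frac_cost_positive`, `frac_effect_positive`, `ci95_cost`,
#'   `ci95_effect` (2.5th/97.5th empirical percentiles).
#' @examples
#' psa <- run_psa(builtin_scenario("duration6"), n_runs = 200, seed = 1)
#' psa$frac_cost_positive
#' @export
run_psa <- function(scenario, n_runs = 5000, seed = 1L,
                    interval_factor = 3.92) {
  validate_scenario(scenario)
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1) {
    stop("n_runs must be >= 1", call. = FALSE)
  }
  n_runs <- as.integer(n_runs)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)

  draw_strategy <- function(s) {
    lapply(stats::setNames(nm = names(.STRATEGY_FIELDS)), function(f) {
      .sample_input(s[[f]], n_runs, interval_factor)
    })
  }
  di <- draw_strategy(scenario$intervention)
  dc <- draw_strategy(scenario$comparator)
  gi <- .sample_input(scenario$shared$gi_event_cost, n_runs, interval_factor)
  h <- scenario$shared$horizon_months

  eval_arm <- function(d) {
    .cohort_eval(
      monthly_cost    = d$monthly_drug_cost + d$monthly_supply_cost,
      p_disc_early    = d$p_disc_early,
      p_disc_late     = d$p_disc_late,
      p_any_teae      = d$p_any_teae,
      p_gi_given_teae = d$p_gi_given_teae,
      gi_event_cost   = gi,
      full_reduction  = d$hba1c_reduction,
      horizon_months  = h)
  }
  oi <- eval_arm(di)
  oc <- eval_arm(dc)

  delta_cost <- oi$total_cost - oc$total_cost
  delta_effect <- oi$hba1c_reduction - oc$hba1c_reduction
  structure(list(
    n_runs = n_runs,
    seed = as.integer(seed),
    interval_factor = interval_factor,
    horizon_months = h,
    draws = data.frame(run = seq_len(n_runs),
                       delta_cost = delta_cost,
                       delta_effect = delta_effect),
    intervention_draws = as.data.frame(oi),
    comparator_draws = as.data.frame(oc),
    frac_cost_positive = mean(delta_cost > 0),
    frac_effect_positive = mean(delta_effect > 0),
    ci95_cost = credible_interval(delta_cost, 0.95),
    ci95_effect = credible_interval(delta_effect, 0.95)),
    class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the probability that the
#' intervention is the cost-effective choice, estimated as the fraction of
#' PSA draws with positive net monetary benefit
#' (`lambda * delta_effect - delta_cost > 0`).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty numeric vector of willingness-to-pay values
#'   (USD per 1% HbA1c reduction).
#' @return A data frame with columns `wtp` and `probability`.
#' @export
ceac_curve <- function(psa, wtp_grid) {
  if (!inherits(psa, "psa_result")) {
    stop("ceac_curve() expects a psa_result", call. = FALSE)
  }
  if (nrow(psa$draws) == 0L) stop("psa has no draws", call. = FALSE)
  if (length(wtp_grid) == 0L) stop("wtp_grid is empty", call. = FALSE)
  de <- psa$draws$delta_effect
  dc <- psa$draws$delta_cost
  prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), 0)
  data.frame(wtp = as.numeric(wtp_grid), probability = prob)
}

#' Acceptability-curve crossover
#'
#' The smallest willingness-to-pay grid value at which the acceptability
#' curve reaches the given probability threshold.
#'
#' @param ceac A data frame from [ceac_curve()].
#' @param threshold Probability threshold (default 0.5).
#' @return A willingness-to-pay value, or `NA` if the curve never reaches
#'   the threshold on the grid.
#' @export
ceac_crossover <- function(ceac, threshold = 0.5) {
  hit <- which(ceac$probability >= threshold)
  if (length(hit) == 0L) NA_real_ else ceac$wtp[[min(hit)]]
}

#' Empirical credible interval
#'
#' Central empirical quantile interval at the given level, using the
#' linear-interpolation quantile definition (type 7): bounds at
#' `(1 - level)/2` and `1 - (1 - level)/2`.
#'
#' @param values Non-empty numeric vector.
#' @param level Coverage in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' credible_interval(1:100, 0.95) # c(3.475, 97.525)
#' @export
credible_interval <- function(values, level = 0.95) {
  if (length(values) == 0L) stop("values is empty", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)", call. = FALSE)
  }
  a <- (1 - level) / 2
  unname(stats::quantile(values, c(a, 1 - a), names = FALSE, type = 7))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d runs, seed %d, %d-month horizon\n",
              x$n_runs, x$seed, x$horizon_months))
  cat(sprintf("  P(dCost > 0)   %.3f   95%% CI [$%.0f, $%.0f]\n",
              x$frac_cost_positive, x$ci95_cost[1], x$ci95_cost[2]))
  cat(sprintf("  P(dEffect > 0) %.3f   95%% CI [%.3f%%, %.3f%%]\n",
              x$frac_effect_positive, x$ci95_effect[1], x$ci95_effect[2]))
  invisible(x)
}
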