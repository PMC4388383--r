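test_that("beta fit matches moment arithmetic and round-trips", {
  # s = (0.696 - 0.304) / 3.92 = 0.1, m(1-m)/s^2 - 1 = 24 -> (12, 12)
  expect_equal(beta_from_interval(0.5, 0.304, 0.696),
               c(alpha = 12, beta = 12), tolerance = 1e-12)

  ab <- beta_from_interval(0.1323, 0.1059, 0.1588)
  expect_equal(unname(ab), c(83.24, 545.93), tolerance = 0.005)

  # round-trip: fitted mean and sd reproduce the interval summaries
  rows <- list(c(0.1323, 0.1059, 0.1588), c(0.6139, 0.4911, 0.7367),
               c(0.547, 0.4378, 0.6566), c(0.0333, 0.0266, 0.04),
               c(0.0978, 0.0782, 0.1174))
  for (r in rows) {
    ab <- beta_from_interval(r[1], r[2], r[3])
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    expect_equal(a / (a + b), r[1], tolerance = 1e-9)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))),
                 (r[3] - r[2]) / 3.92, tolerance = 1e-9)
  }

  expect_error(beta_from_interval(0.5, 0.6, 0.7), "<=")
  expect_error(beta_from_interval(0.5, 0.5, 0.5), "low < high")
  expect_warning(beta_from_interval(0.5, 0, 1, interval_factor = 1.5),
                 "clamped")
})

test_that("zero-probability inputs stay stochastic under the edge rule", {
  # mean moved to high/2, sd = high/factor
  ab <- beta_from_interval(0, 0, 0.01)
  a <- ab[["alpha"]]; b <- ab[["beta"]]
  expect_equal(a / (a + b), 0.005, tolerance = 1e-9)
  expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), 0.01 / 3.92,
               tolerance = 1e-9)
})

test_that("normal fit takes mu = point, sigma = range / factor", {
  expect_equal(normal_from_interval(407, 367, 448),
               c(mu = 407, sigma = 81 / 3.92))
  expect_equal(normal_from_interval(1113, 890, 1335),
               c(mu = 1113, sigma = 445 / 3.92))
  expect_equal(normal_from_interval(407, 367, 448, interval_factor = 2),
               c(mu = 407, sigma = 40.5))
  expect_error(normal_from_interval(100, 100, 100), "low < high")
})

test_that("sampled parameters respect their domains", {
  d6 <- builtin_scenario("duration6")
  psa <- run_psa(d6, n_runs = 2000, seed = 11)
  for (arm in c("intervention_draws", "comparator_draws")) {
    d <- psa[[arm]]
    expect_true(all(d$retention_early >= 0 & d$retention_early <= 1))
    expect_true(all(d$retention_full <= d$retention_early))
    expect_true(all(d$drug_cost >= 0))
    expect_true(all(d$ae_cost >= 0))
    expect_true(all(d$hba1c_reduction >= 0))
  }
})

test_that("PSA is deterministic in the seed and restores the RNG state", {
  d6 <- builtin_scenario("duration6")
  a <- run_psa(d6, n_runs = 200, seed = 5)
  b <- run_psa(d6, n_runs = 200, seed = 5)
  expect_identical(a$draws, b$draws)
  c_ <- run_psa(d6, n_runs = 200, seed = 6)
  expect_false(identical(a$draws$delta_cost, c_$draws$delta_cost))

  # the caller's stream is unperturbed by the seeded block
  set.seed(123)
  reference <- runif(5)
  set.seed(123)
  first <- runif(2)
  run_psa(d6, n_runs = 50, seed = 5)
  rest <- runif(3)
  expect_identical(c(first, rest), reference)
})

test_that("a fully degenerate scenario collapses the PSA onto the base case", {
  scn <- degenerate_scenario()
  bc <- base_case_table(scn)
  psa <- run_psa(scn, n_runs = 50, seed = 3)
  expect_true(all(psa$draws$delta_cost == bc$total_cost[3]))
  expect_true(all(psa$draws$delta_effect == bc$hba1c_reduction[3]))
  expect_equal(psa$ci95_cost, rep(bc$total_cost[3], 2))

  # CEAC becomes an exact step at the base-case ICER
  icer <- bc$icer[3]
  grid <- c(icer - 200, icer - 1, icer + 1, icer + 200)
  ce <- ceac_curve(psa, grid)
  expect_equal(ce$probability, c(0, 0, 1, 1))
})

test_that("CEAC lies in [0,1] and is monotone when every draw gains effect", {
  d6 <- builtin_scenario("duration6")
  psa <- run_psa(d6, n_runs = 1000, seed = 7)
  ce <- ceac_curve(psa, seq(0, 5000, 100))
  expect_true(all(ce$probability >= 0 & ce$probability <= 1))
  if (all(psa$draws$delta_effect > 0)) {
    expect_true(all(diff(ce$probability) >= 0))
  }
  # lambda = 0: probability the intervention is cheaper
  expect_equal(ce$probability[ce$wtp == 0], mean(psa$draws$delta_cost < 0))
  expect_error(ceac_curve(psa, numeric(0)), "empty")
})

test_that("conservation holds in every PSA draw", {
  for (label in c("duration6", "meta_analysis")) {
    psa <- run_psa(builtin_scenario(label), n_runs = 500, seed = 13)
    for (arm in c("intervention_draws", "comparator_draws")) {
      d <- psa[[arm]]
      expect_equal(d$total_cost, d$drug_cost + d$ae_cost + d$disc_cost)
    }
  }
})

test_that("tornado endpoints equal brute-force re-evaluation", {
  scn <- builtin_scenario("duration6")
  tw <- one_way_sweep(scn, "delta_cost")
  expect_equal(nrow(tw), 15) # 7 inputs per strategy + the shared GI cost

  brute <- function(role, field, value) {
    s2 <- scn
    s2[[role]][[field]]$point <- value
    oi <- evaluate_strategy(s2$intervention, s2$shared)
    oc <- evaluate_strategy(s2$comparator, s2$shared)
    oi$total_cost - oc$total_cost
  }
  for (i in seq_len(nrow(tw))) {
    parts <- strsplit(tw$input[i], ".", fixed = TRUE)[[1]]
    u <- scn[[parts[1]]][[parts[2]]]
    expect_identical(tw$outcome_at_low[i], brute(parts[1], parts[2], u$low))
    expect_identical(tw$outcome_at_high[i], brute(parts[1], parts[2], u$high))
  }

  # sorted by width, degenerate inputs last with width 0
  expect_true(all(diff(tw$width) <= 0))
  expect_equal(tw$width[tw$input == "comparator.monthly_supply_cost"], 0)

  # hand-computed widths: exenatide drug cost scales linearly in its price
  r <- tw[tw$input == "comparator.monthly_drug_cost", ]
  expect_equal(r$width, (448 - 367) * (0.1323 * 3 + 0.8677 * 6),
               tolerance = 1e-9)
  g <- tw[tw$input == "shared.gi_event_cost", ]
  expect_equal(g$width, (0.6489 * 0.547 - 0.6139 * 0.3993) * (1335 - 890),
               tolerance = 1e-9)

  # top-k filter
  expect_equal(nrow(one_way_sweep(scn, "delta_cost", top_k = 10)), 10)

  # the effect sweep ranks the effectiveness inputs first
  te <- one_way_sweep(scn, "delta_effect")
  expect_true(all(c("intervention.hba1c_reduction",
                    "comparator.hba1c_reduction") %in% te$input[1:4]))
})

test_that("credible intervals use linear-interpolation quantiles", {
  expect_equal(credible_interval(1:100, 0.95), c(3.475, 97.525))
  expect_equal(credible_interval(rep(7, 10)), c(7, 7))
  # pinned by the documented type-7 definition
  v <- rep(c(0, 1), 50)
  expect_equal(credible_interval(v, 0.5),
               unname(quantile(v, c(0.25, 0.75), type = 7)))
  expect_error(credible_interval(numeric(0)), "empty")
  expect_error(credible_interval(1:10, 1.2), "\\(0, 1\\)")
})

test_that("the interval-interpretation factor widens sampled spreads", {
  d6 <- builtin_scenario("duration6")
  tight <- run_psa(d6, n_runs = 2000, seed = 21, interval_factor = 3.92)
  wide <- run_psa(d6, n_runs = 2000, seed = 21, interval_factor = 2)
  expect_gt(diff(wide$ci95_effect), diff(tight$ci95_effect))
  expect_gt(diff(wide$ci95_cost), diff(tight$ci95_cost))
})
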