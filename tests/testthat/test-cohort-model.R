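# Expected values below were hand-derived from the stated accrual rules
# (early discontinuers pay 1 month, late discontinuers 3 months, completers
# the horizon; AE cost is a three-way product; effect is retention-scaled)
# and are independently confirmed by the patient-level micro-simulation in
# test-synthetic-oracle.R.

test_that("retention fractions follow the sequential tree", {
  expect_equal(retention_fractions(0, 0.1323),
               list(retention_early = 1, retention_full = 0.8677))
  expect_equal(retention_fractions(0, 0),
               list(retention_early = 1, retention_full = 1))
  r <- retention_fractions(0.0333, 0.0978)
  expect_equal(r$retention_early, 0.9667)
  expect_equal(r$retention_full, 0.9667 * 0.9022, tolerance = 1e-12)
  expect_error(retention_fractions(1.2, 0.1), "probability")
  expect_error(retention_fractions(0.1, -0.1), "probability")
})

test_that("expected drug cost matches the stratum accrual rules", {
  expect_equal(expected_drug_cost(407, 0, 0.1323, 6), 2280.4617)
  expect_equal(expected_drug_cost(545, 0.0333, 0.0978, 6), 3024.6792699,
               tolerance = 1e-9)
  expect_equal(expected_drug_cost(100, 0, 0, 6), 600)
  expect_equal(expected_drug_cost(100, 1, 0, 6), 100) # all stop at 1 month
  expect_error(expected_drug_cost(100, 0, 0, 7), "6 or 12")
  expect_error(expected_drug_cost(-1, 0, 0, 6), ">= 0")
})

test_that("expected adverse-event cost is the three-way product", {
  expect_equal(expected_ae_cost(0.6139, 0.3993, 1113), 272.8299905,
               tolerance = 1e-9)
  expect_equal(round(expected_ae_cost(0.6139, 0.3993, 1113)), 273)
  expect_equal(expected_ae_cost(0.6489, 0.547, 1113), 395.0574579,
               tolerance = 1e-9)
  expect_equal(expected_ae_cost(0, 0.9, 1113), 0)
  expect_error(expected_ae_cost(1.1, 0.5, 100), "probability")
})

test_that("expected effect is retention-scaled with baseline return", {
  expect_equal(expected_effect(1.28, 0.8677), 1.110656)
  expect_equal(expected_effect(1.48, 1), 1.48)
  expect_equal(expected_effect(1.18, 0.9667 * 0.9022), 1.0291449532,
               tolerance = 1e-9)
  expect_error(expected_effect(-1, 0.5), ">= 0")
})

test_that("evaluate_strategy composes the branches and conserves cost", {
  d6 <- builtin_scenario("duration6")
  ox <- evaluate_strategy(d6$comparator, d6$shared)
  expect_equal(ox$drug_cost, 2280.4617)
  expect_equal(ox$ae_cost, 272.8299905, tolerance = 1e-9)
  expect_equal(ox$disc_cost, 0)
  expect_equal(ox$total_cost, ox$drug_cost + ox$ae_cost + ox$disc_cost)
  expect_equal(ox$hba1c_reduction, 1.110656)

  ol <- evaluate_strategy(d6$intervention, d6$shared)
  expect_equal(ol$drug_cost, 3024.6792699, tolerance = 1e-9)
  expect_equal(ol$ae_cost, 395.0574579, tolerance = 1e-9)
  expect_equal(ol$total_cost, 3419.7367278, tolerance = 1e-9)
  expect_equal(ol$hba1c_reduction, 0.9667 * 0.9022 * 1.48, tolerance = 1e-12)

  # all costs zero => total zero
  z <- d6
  z$intervention$monthly_drug_cost <- uncertain_input(0, family = "fixed")
  z$intervention$monthly_supply_cost <- uncertain_input(0, family = "fixed")
  z$shared$gi_event_cost <- uncertain_input(0, family = "fixed")
  expect_equal(evaluate_strategy(z$intervention, z$shared)$total_cost, 0)
})

test_that("cohort expectations are monotone and bounded", {
  for (seed in 1:10) {
    scn <- random_scenario(seed)
    s <- scn$intervention
    m <- s$monthly_drug_cost$point + s$monthly_supply_cost$point
    pe <- s$p_disc_early$point
    pl <- s$p_disc_late$point
    # nondecreasing in monthly cost and horizon; bounded by full accrual
    expect_lte(expected_drug_cost(m, pe, pl, 6),
               expected_drug_cost(m * 1.1, pe, pl, 6))
    expect_lte(expected_drug_cost(m, pe, pl, 6),
               expected_drug_cost(m, pe, pl, 12))
    expect_lte(expected_drug_cost(m, pe, pl, 6), 6 * m)
    expect_lte(expected_drug_cost(m, pe, pl, 12), 12 * m)
    # effect nondecreasing in retention
    r <- retention_fractions(pe, pl)$retention_full
    expect_lte(expected_effect(s$hba1c_reduction$point, r * 0.9),
               expected_effect(s$hba1c_reduction$point, r))
    # retention ordering
    o <- evaluate_strategy(s, scn$shared)
    expect_lte(o$retention_full, o$retention_early)
    expect_gte(o$retention_full, 0)
    expect_lte(o$retention_early, 1)
    expect_lte(o$hba1c_reduction, s$hba1c_reduction$point)
  }
})

test_that("only completers accrue the extra 6 months of drug cost", {
  for (label in c("duration6", "meta_analysis")) {
    scn <- builtin_scenario(label)
    for (role in c("intervention", "comparator")) {
      s <- scn[[role]]
      o6 <- evaluate_strategy(s, scn$shared, 6L)
      o12 <- evaluate_strategy(s, scn$shared, 12L)
      m <- s$monthly_drug_cost$point + s$monthly_supply_cost$point
      expect_equal(o12$total_cost - o6$total_cost,
                   o6$retention_full * 6 * m, tolerance = 1e-9)
      # AE cost incurred once; effect unchanged across horizons
      expect_equal(o12$ae_cost, o6$ae_cost)
      expect_equal(o12$hba1c_reduction, o6$hba1c_reduction)
    }
  }
})
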