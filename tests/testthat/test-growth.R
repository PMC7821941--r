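test_that("cell counts follow doubling kinetics", {
  expect_equal(cells_at_time(3e11, 24, 0), 3e11)
  expect_equal(cells_at_time(3e11, 24, 24), 6e11)
  expect_equal(cells_at_time(1e12, 24, 72), 8e12)
  # stepwise trajectory holds the count constant within a period
  expect_equal(cells_at_time(1e12, 24, 35, "stepwise"), 2e12)
  expect_error(cells_at_time(1e12, 0, 10), "doubling_time")
})

test_that("batch time adds the growth phase to maturation", {
  expect_equal(batch_time(24, 0, 240), 240)
  expect_equal(batch_time(8, log2(100), 24), 8 * log2(100) + 24,
               tolerance = 1e-12)
  expect_equal(batch_time(8, log2(100), 24), 77.1508, tolerance = 1e-4)
  expect_equal(batch_time(24, log2(100), 240), 399.4525, tolerance = 1e-4)
})

test_that("batch mass respects the cell packing bound", {
  expect_equal(batch_mass(1e7, 20, 5e-15, 1060), 1060)
  expect_equal(batch_mass(0, 20, 5e-15, 1060), 0)
  # exactly at full packing (volume fraction 1) must be accepted
  expect_equal(batch_mass(2e8, 20, 5e-15, 1060), 21200)
  expect_error(batch_mass(2e8 * 1.01, 20, 5e-15, 1060),
               "operating capacity")
  # monotone nondecreasing in each driver
  base <- batch_mass(5e7, 20, 5e-15, 1060)
  expect_gte(batch_mass(6e7, 20, 5e-15, 1060), base)
  expect_gte(batch_mass(5e7, 25, 5e-15, 1060), base)
  expect_gte(batch_mass(5e7, 20, 6e-15, 1060), base)
  expect_gte(batch_mass(5e7, 20, 5e-15, 1100), base)
})

test_that("continuous growth-phase glucose matches numerical quadrature", {
  set.seed(101)
  for (i in 1:100) {
    r <- runif(1, 1e-14, 1e-12)
    n0 <- 10^runif(1, 10, 14)
    td <- runif(1, 4, 48)
    dur <- runif(1, 0, 7 * td)
    closed <- glucose_growth_phase(r, n0, td, dur, "continuous")
    quad <- trapezoid(function(t) r * n0 * 2^(t / td), dur, n = 1e4)
    if (dur == 0) {
      expect_identical(closed, 0)
    } else {
      expect_equal(closed, quad, tolerance = 1e-6)
    }
  }
})

test_that("stepwise growth-phase glucose matches per-period summation", {
  set.seed(202)
  for (i in 1:50) {
    r <- runif(1, 1e-14, 1e-12)
    n0 <- 10^runif(1, 10, 14)
    td <- runif(1, 4, 48)
    dur <- runif(1, 0, 7 * td)
    expect_equal(glucose_growth_phase(r, n0, td, dur, "stepwise"),
                 stepwise_glucose_sum(r, n0, td, dur), tolerance = 1e-12)
  }
  expect_equal(glucose_growth_phase(4.13e-13, 1e12, 24, 0), 0)
})

test_that("continuous closed form evaluates the published-style example", {
  # one doubling period: r * N0 * (td/ln2) * (2 - 1)
  expect_equal(glucose_growth_phase(4.13e-13, 1e12, 24, 24, "continuous"),
               4.13e-13 * 1e12 * 24 / log(2), tolerance = 1e-12)
  expect_equal(glucose_growth_phase(4.13e-13, 1e12, 24, 24, "continuous"),
               14.30, tolerance = 1e-3)
})

test_that("maturation glucose is the rate-count-time product", {
  expect_equal(glucose_maturation_phase(4.13e-14, 4e15, 0), 0)
  expect_equal(glucose_maturation_phase(4.13e-14, 4e15, 24), 3964.8)
  expect_equal(glucose_maturation_phase(4.13e-14, 4e15, 48),
               2 * glucose_maturation_phase(4.13e-14, 4e15, 24))
})

test_that("oxygen demand covers the initial charge plus consumption", {
  p <- scenario_preset("scenario1")
  plan <- batch_plan(p)
  # stoichiometric mode equals the 6:1 oracle on total glucose
  o2 <- oxygen_demand(plan, p, "stoichiometric")
  expect_equal(o2$consumed,
               oxygen_from_stoichiometry(plan$glucose_total, 6))
  expect_equal(o2$total, o2$initial_charge + 6 * plan$glucose_total)
  # zero cells: initial charge only
  p0 <- acbm_scenario(achievable_cell_concentration = 0)
  plan0 <- batch_plan(p0)
  expect_equal(plan0$oxygen_consumed, 0)
  expect_gt(plan0$oxygen_initial_charge, 0)
  expect_equal(plan0$oxygen_total, plan0$oxygen_initial_charge)
  # consumption scales linearly with cell number (concentration)
  pk <- acbm_scenario(achievable_cell_concentration =
                        2 * p$achievable_cell_concentration)
  expect_equal(batch_plan(pk)$oxygen_consumed, 2 * plan$oxygen_consumed)
})

test_that("metabolic heat is proportional to oxygen consumed", {
  expect_equal(metabolic_heat(1, 470), 470)
  expect_equal(metabolic_heat(0, 470), 0)
  expect_equal(metabolic_heat(10, 470), 4700)
})

test_that("batch plan satisfies its structural invariants", {
  for (nm in scenario_names()) {
    p <- load_scenario(nm)
    plan <- batch_plan(p)
    expect_equal(plan$batch_time,
                 plan$growth_phase_duration + p$maturation_time, info = nm)
    expect_equal(plan$glucose_total,
                 plan$glucose_growth + plan$glucose_maturation, info = nm)
    expect_equal(plan$final_cell_count,
                 plan$initial_cell_count * 2^plan$doublings,
                 tolerance = 1e-12, info = nm)
    expect_lte(plan$batch_mass,
               p$bioreactor_working_volume * p$cell_density * (1 + 1e-12))
  }
})
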