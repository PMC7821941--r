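test_that("media volume charging handles the boundary cases", {
  # no glucose demand: the initial vessel fill is still one charge
  md <- media_volume_per_batch(0, 3.56e-2, 20000)
  expect_equal(md$charges, 1)
  expect_equal(md$volume_per_batch, 20000)
  # raw volume exactly two working volumes is exactly two charges
  md2 <- media_volume_per_batch(2 * 20000 * 3.56e-2, 3.56e-2, 20000)
  expect_equal(md2$charges, 2)
  expect_equal(md2$volume_per_batch, 40000)
  # fractional policy tracks the raw requirement; ceiling rounds up
  mdf <- media_volume_per_batch(5853, 3.56e-2, 20000)
  expect_equal(mdf$raw_volume, 5853 / 3.56e-2)
  expect_equal(mdf$volume_per_batch, mdf$raw_volume)
  mdc <- media_volume_per_batch(5853, 3.56e-2, 20000, "ceiling")
  expect_equal(mdc$charges, ceiling(mdf$raw_volume / 20000))
  expect_error(media_volume_per_batch(100, 0, 20000),
               "glucose_concentration")
})

test_that("media cost per litre sums basal and growth-factor terms", {
  # baseline FGF-2 contribution alone is 205 USD/L
  expect_equal(media_cost_per_liter(0, 1.00e-4, 2.05e6), 205)
  expect_equal(media_cost_per_liter(0.24, 0, 0, 0, 0), 0.24)
  expect_equal(media_cost_per_liter(10, 1e-4, 2.05e6, 2e-6, 8.09e7),
               376.80, tolerance = 1e-10)
})

test_that("thermal energy terms follow m.cp.dT", {
  expect_equal(heating_energy(1, 1, 4.184, 20, 37), 71.128)
  expect_equal(heating_energy(1, 1, 4.184, 20, 20), 0)
  expect_equal(heating_energy(2, 1, 4.184, 20, 37),
               2 * heating_energy(1, 1, 4.184, 20, 37))
  expect_error(heating_energy(1, 1, 4.184, 37, 20), "t_target")

  expect_equal(bioreactor_heat_removal(470, 1), 470)
  expect_equal(bioreactor_heat_removal(470, 0.5), 940)
  expect_equal(bioreactor_heat_removal(0, 0.9), 0)
  expect_error(bioreactor_heat_removal(470, 0), "efficiency")

  expect_equal(acbm_cooling_energy(1, 2.24, 37, 4, 1.0), 73.92)
  expect_equal(acbm_cooling_energy(0, 2.24, 37, 4, 1.0), 0)
  expect_equal(acbm_cooling_energy(1060, 2.24, 37, 4, 1.0), 78355.2)
  expect_error(acbm_cooling_energy(1, 2.24, 4, 37, 1.0), "t_hot")
})

test_that("the electricity price is the cheapest available source", {
  m <- energy_price_model()
  # the refit on the packaged table reproduces a least-squares oracle
  tab <- default_energy_table()
  fit <- lm(electricity_usd_per_kwh ~ gas_usd_per_kcf, data = tab)
  expect_equal(m$grid_slope, unname(coef(fit)[2]))
  expect_equal(m$grid_intercept, unname(coef(fit)[1]))
  expect_gt(m$grid_slope, 0)

  # onsite generation undercuts the grid at moderate gas prices
  gas <- 6.4
  grid <- m$grid_slope * gas + m$grid_intercept
  onsite <- gas / (m$gas_energy_content * m$turbine_efficiency)
  expect_equal(electricity_price(gas, m), min(grid, onsite))
  # at very high gas prices the grid line is the minimum
  expect_equal(electricity_price(50, m),
               min(m$grid_slope * 50 + m$grid_intercept,
                   50 / (m$gas_energy_content * m$turbine_efficiency)))
  # solar, when enabled, has zero operating cost and wins
  ms <- energy_price_model(solar_enabled = TRUE)
  expect_equal(electricity_price(gas, ms), 0)
  expect_error(electricity_price(-1, m), "gas_price")
})

test_that("water is charged in as process water and out as wastewater", {
  expect_equal(water_costs(0, 1e-4, 5e-4), 0)
  expect_equal(water_costs(1e6, 2e-4, 3e-4), 1e6 * 5e-4)
  expect_equal(water_costs(5e5, 2e-4, 3e-4),
               water_costs(1e6, 2e-4, 3e-4) / 2)
})

test_that("labor and fixed manufacturing costs scale linearly", {
  expect_equal(labor_cost(0, 13.68, 8760, 1.75), 0)
  expect_equal(labor_cost(50, 13.68, 8760, 1.75, 1),
               50 * 13.68 * 8760 * 1.75)
  expect_equal(labor_cost(100, 13.68, 8760, 1.75),
               2 * labor_cost(50, 13.68, 8760, 1.75))
  expect_equal(fixed_manufacturing_cost(1e6, 0.1), 1e5)
  expect_equal(fixed_manufacturing_cost(1e6, 0), 0)
  expect_equal(fixed_manufacturing_cost(2e6, 0.05),
               2 * fixed_manufacturing_cost(1e6, 0.05))
  expect_error(fixed_manufacturing_cost(1e6, 1), "fraction")
})

test_that("operating total is the exact sum of the six items", {
  oc <- operating_costs(load_scenario("scenario2"))
  items <- c(oc$media, oc$oxygen, oc$energy, oc$water, oc$labor,
             oc$fixed_manufacturing)
  expect_equal(oc$total, sum(items))
  # permutation-invariant re-summation oracle
  set.seed(7)
  expect_equal(oc$total, sum(sample(items)))
  expect_equal(total_operating(oc), oc$total)
})

test_that("media dominates operating cost in the growth-factor scenarios", {
  for (nm in c("scenario1", "scenario2", "scenario3")) {
    oc <- operating_costs(load_scenario(nm))
    others <- oc$oxygen + oc$energy + oc$water + oc$labor +
      oc$fixed_manufacturing
    expect_gt(oc$media, others, label = nm)
  }
})

test_that("cost items are monotone in their driving quantities", {
  base <- cost_breakdown("scenario2")
  bump <- function(nm, f = 1.2) {
    p <- load_scenario("scenario2")
    p[[nm]] <- p[[nm]] * f
    cost_breakdown(p)
  }
  expect_gt(bump("basal_media_cost")$operating$media, base$operating$media)
  expect_gt(bump("oxygen_cost")$operating$oxygen, base$operating$oxygen)
  expect_gt(bump("process_water_cost")$operating$water,
            base$operating$water)
  expect_gt(bump("base_wage")$operating$labor, base$operating$labor)
  expect_gt(bump("fixed_manufacturing_fraction")$operating$fixed_manufacturing,
            base$operating$fixed_manufacturing)
})
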