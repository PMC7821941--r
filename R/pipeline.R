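# Vectorized end-to-end price evaluation.
#
# The sensitivity algorithms need tens of thousands of model evaluations,
# so the full pipeline is evaluated on columns of a parameter matrix in
# one pass. Rows violating scenario invariants (e.g. the cell packing
# bound) are flagged and priced NA rather than silently dropped. A
# consistency test pins this path to cost_breakdown() on the presets.

price_pipeline <- function(p, energy_model,
                           trajectory = "stepwise",
                           charge_policy = "fractional") {
  frac <- cell_volume_fraction(p$achievable_cell_concentration,
                               p$cell_volume)
  violation <- frac > 1 + 1e-12
  # violating rows are computed with a placeholder concentration so the
  # arithmetic stays finite, then masked to NA at the end
  conc <- ifelse(violation, 1e6, p$achievable_cell_concentration)

  doublings <- growth_doublings(p$inoculum_fraction)
  growth_h <- doublings * p$hours_per_doubling
  bt <- batch_time(p$hours_per_doubling, doublings, p$maturation_time)
  final_n <- conc * 1e6 * p$bioreactor_working_volume
  init_n <- final_n * p$inoculum_fraction
  mass <- final_n * p$cell_volume * p$cell_density

  cell_hours <- cell_hours_growth(init_n, p$hours_per_doubling, doublings,
                                  trajectory) +
    final_n * p$maturation_time
  glc <- p$glucose_consumption_per_cell *
    cell_hours_growth(init_n, p$hours_per_doubling, doublings, trajectory) +
    glucose_maturation_phase(p$glucose_consumption_per_cell, final_n,
                             p$maturation_time)

  wv_l <- p$bioreactor_working_volume * 1e3
  o2_batch <- initial_oxygen_charge(wv_l, p$o2_steady_state_fraction,
                                    p$o2_molar_volume) +
    p$oxygen_uptake_per_cell * cell_hours
  o2_consumed <- p$oxygen_uptake_per_cell * cell_hours

  bpy <- batches_per_year(p$operating_hours_per_year, bt)
  count <- pmax(round(p$annual_production_mass / (mass * bpy)), 1)
  annual_batches <- bpy * count
  annual_mass <- mass * annual_batches

  unit <- equipment_cost(p$bioreactor_working_volume, p$equipment_unit_cost,
                         p$scaling_exponent, p$cepci_adjustment,
                         p$lang_factor)
  capex <- unit * count

  md <- media_volume_per_batch(glc, p$glucose_concentration, wv_l,
                               charge_policy)
  annual_volume <- md$volume_per_batch * annual_batches
  cost_l <- media_cost_per_liter(p$basal_media_cost, p$fgf2_concentration,
                                 p$fgf2_cost, p$tgfb_concentration,
                                 p$tgfb_cost)
  media <- annual_volume * cost_l
  oxygen <- o2_batch * annual_batches * p$oxygen_cost

  heat_kwh <- heating_energy(annual_volume, p$media_density,
                             p$media_specific_heat,
                             p$media_inlet_temperature,
                             p$culture_temperature) / 3600
  removal_kwh <- metabolic_heat(o2_consumed * annual_batches,
                                p$heat_per_mol_o2) /
    p$heat_exchanger_efficiency / 3600
  cooling_kwh <- annual_mass * p$acbm_specific_heat *
    (p$acbm_outlet_temperature - p$acbm_chilled_temperature) /
    p$heat_exchanger_efficiency / 3600
  grid <- energy_model$grid_slope * p$natural_gas_price +
    energy_model$grid_intercept
  onsite <- p$natural_gas_price / (p$gas_energy_content *
                                     p$turbine_efficiency)
  elec <- pmin(grid, onsite)
  energy <- (heat_kwh + removal_kwh + cooling_kwh) * elec

  water <- water_costs(annual_volume, p$process_water_cost,
                       p$wastewater_cost)
  labor <- labor_cost(count, p$base_wage, p$operating_hours_per_year,
                      p$labor_correction_factor, p$laborers_per_bioreactor)
  fixed <- capex * p$fixed_manufacturing_fraction

  annualized <- annualize_capital(capex, pmin(p$debt_fraction, 1),
                                  p$loan_interest_rate,
                                  p$equity_interest_rate,
                                  pmax(p$repayment_period, 1))
  total <- annualized + media + oxygen + energy + water + labor + fixed
  price <- total / annual_mass
  price[violation] <- NA_real_
  attr(price, "violation") <- violation
  price
}

#' Evaluate the price model on a matrix of parameter draws
#'
#' Each row of `samples` is one parameter vector; columns must be named
#' registry parameters. Parameters not present in `samples` are filled
#' from `base`. Rows violating scenario invariants (the cell packing
#' bound) are flagged via the `"violation"` attribute and priced `NA`
#' rather than dropped.
#'
#' @param samples Matrix or data.frame of parameter draws, columns named.
#' @param base Scenario supplying the non-varied parameters (default the
#'   baseline preset).
#' @param energy_model Optional [energy_price_model()]; default built from
#'   `base`.
#' @return Numeric vector of minimum prices (USD/kg), one per row, with a
#'   logical `"violation"` attribute.
#' @export
#' @examples
#' X <- matrix(c(240, 24), 1, dimnames = list(NULL,
#'   c("maturation_time", "hours_per_doubling")))
#' evaluate_model_batch(X)
evaluate_model_batch <- function(samples, base = scenario_preset("scenario1"),
                                 energy_model = NULL) {
  validate_scenario(base)
  samples <- as.data.frame(samples)
  reg <- param_registry()
  bad <- setdiff(names(samples), reg$parameter)
  if (length(bad)) {
    stop("unknown parameter column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(energy_model)) {
    energy_model <- energy_price_model(
      gas_energy_content = base$gas_energy_content,
      turbine_efficiency = base$turbine_efficiency,
      solar_enabled = base$solar_enabled)
  }
  n <- nrow(samples)
  p <- lapply(stats::setNames(reg$parameter, reg$parameter), function(nm) {
    if (nm %in% names(samples)) samples[[nm]] else rep.int(base[[nm]], n)
  })
  price <- price_pipeline(p, energy_model)
  if (any(attr(price, "violation"))) {
    warning(sum(attr(price, "violation")),
            " row(s) violate the cell packing bound; priced NA",
            call. = FALSE)
  }
  price
}
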