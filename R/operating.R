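# Itemized annual operating expenses.

#' Media demand for one batch
#'
#' The glucose requirement sets the raw media volume
#' (`glucose_total / glucose_concentration`). Volume is delivered in
#' "charges", one charge being one bioreactor working volume. By default
#' charges are fractional with a minimum of one (the initial vessel fill);
#' `"ceiling"` rounds up to whole charges.
#'
#' @param glucose_total Glucose required per batch, mol.
#' @param glucose_concentration Glucose concentration of the medium, mol/L.
#' @param working_volume Working volume in litres.
#' @param charge_policy `"fractional"` (default) or `"ceiling"`.
#' @return List with `raw_volume` (L), `charges` and `volume_per_batch`
#'   (delivered litres).
#' @export
#' @examples
#' media_volume_per_batch(5853, 3.56e-2, 20000)
media_volume_per_batch <- function(glucose_total, glucose_concentration,
                                   working_volume,
                                   charge_policy = c("fractional",
                                                     "ceiling")) {
  charge_policy <- match.arg(charge_policy)
  stopifnot(all(glucose_total >= 0), all(working_volume > 0))
  if (any(glucose_concentration <= 0)) {
    stop("glucose_concentration must be > 0", call. = FALSE)
  }
  raw <- glucose_total / glucose_concentration
  charges <- raw / working_volume
  charges <- if (charge_policy == "ceiling") ceiling(charges) else charges
  charges <- pmax(charges, 1)
  list(raw_volume = raw, charges = charges,
       volume_per_batch = charges * working_volume)
}

#' Media cost per litre
#'
#' Basal medium plus growth-factor contributions:
#' `basal + fgf2_conc * fgf2_cost + tgfb_conc * tgfb_cost`.
#'
#' @param basal_cost Basal medium cost, USD/L.
#' @param fgf2_conc,fgf2_cost FGF-2 concentration (g/L) and price (USD/g).
#' @param tgfb_conc,tgfb_cost TGF-beta concentration (g/L) and price
#'   (USD/g).
#' @return Cost in USD/L.
#' @export
media_cost_per_liter <- function(basal_cost, fgf2_conc, fgf2_cost,
                                 tgfb_conc = 0, tgfb_cost = 0) {
  stopifnot(all(basal_cost >= 0), all(fgf2_conc >= 0), all(fgf2_cost >= 0),
            all(tgfb_conc >= 0), all(tgfb_cost >= 0))
  basal_cost + fgf2_conc * fgf2_cost + tgfb_conc * tgfb_cost
}

#' Minimum energy to heat the medium
#'
#' `volume * density * specific_heat * (t_target - t_in)`.
#'
#' @param volume Volume in litres.
#' @param density Density in kg/L.
#' @param specific_heat Specific heat in kJ/kg/degC.
#' @param t_in,t_target Inlet and target temperatures, degC
#'   (`t_target >= t_in`).
#' @return Energy in kJ.
#' @export
heating_energy <- function(volume, density, specific_heat, t_in, t_target) {
  stopifnot(all(volume >= 0), all(density >= 0), all(specific_heat >= 0))
  if (any(t_target < t_in)) {
    stop("t_target must be >= t_in", call. = FALSE)
  }
  volume * density * specific_heat * (t_target - t_in)
}

#' Energy input to remove metabolic heat
#'
#' Metabolic heat divided by the cooling-system efficiency gives the
#' electrical-equivalent energy input.
#'
#' @param metabolic_heat Heat to remove, kJ.
#' @param efficiency Cooling-system efficiency in (0, 1].
#' @return Energy input in kJ.
#' @export
bioreactor_heat_removal <- function(metabolic_heat, efficiency) {
  stopifnot(all(metabolic_heat >= 0))
  if (any(efficiency <= 0 | efficiency > 1)) {
    stop("efficiency must be in (0, 1]", call. = FALSE)
  }
  metabolic_heat / efficiency
}

#' Energy to chill the harvested product
#'
#' Product leaving the vessel at culture temperature is chilled for food
#' safety: `mass * specific_heat * (t_hot - t_cold) / efficiency`.
#'
#' @param mass Product mass, kg.
#' @param specific_heat Product specific heat, kJ/kg/degC (2.24 for beef).
#' @param t_hot,t_cold Start and end temperatures, degC (`t_hot > t_cold`).
#' @param efficiency Heat-exchanger efficiency in (0, 1].
#' @return Energy in kJ.
#' @export
#' @examples
#' acbm_cooling_energy(1, 2.24, 37, 4, 1.0)  # 73.92 kJ
acbm_cooling_energy <- function(mass, specific_heat, t_hot, t_cold,
                                efficiency = 1) {
  stopifnot(all(mass >= 0), all(specific_heat >= 0))
  if (any(t_hot <= t_cold)) {
    stop("t_hot must be > t_cold", call. = FALSE)
  }
  if (any(efficiency <= 0 | efficiency > 1)) {
    stop("efficiency must be in (0, 1]", call. = FALSE)
  }
  mass * specific_heat * (t_hot - t_cold) / efficiency
}

#' Electricity price model
#'
#' Grid electricity price is a linear function of the industrial natural
#' gas price, refit by least squares from the packaged price table each
#' time the model is built (rather than hard-coding coefficients). Onsite
#' boiler-turbine generation is priced as fuel cost divided by the energy
#' content and conversion efficiency; solar has zero operating cost and is
#' only considered when enabled.
#'
#' @param table Data frame with columns `electricity_usd_per_kwh` and
#'   `gas_usd_per_kcf`; default is the packaged table.
#' @param gas_energy_content kWh of potential energy per 1000 cubic feet.
#' @param turbine_efficiency Fuel-to-electricity efficiency of the onsite
#'   system.
#' @param solar_enabled Whether zero-operating-cost solar is available.
#' @return Object of class `acbm_energy_model` with `grid_slope`,
#'   `grid_intercept`, `gas_energy_content`, `turbine_efficiency`,
#'   `solar_cost`, `solar_enabled`.
#' @export
energy_price_model <- function(table = NULL, gas_energy_content = 303.6,
                               turbine_efficiency = 0.35,
                               solar_enabled = FALSE) {
  if (is.null(table)) table <- default_energy_table()
  stopifnot(all(c("electricity_usd_per_kwh", "gas_usd_per_kcf") %in%
                  names(table)))
  fit <- stats::lm(electricity_usd_per_kwh ~ gas_usd_per_kcf, data = table)
  structure(list(
    grid_slope = unname(stats::coef(fit)[2]),
    grid_intercept = unname(stats::coef(fit)[1]),
    gas_energy_content = gas_energy_content,
    turbine_efficiency = turbine_efficiency,
    solar_cost = 0,
    solar_enabled = solar_enabled
  ), class = "acbm_energy_model")
}

#' Packaged energy price table
#'
#' Package-constructed estimates of inflation-adjusted national-average
#' industrial electricity and natural-gas prices, 1999-2019, used to fit
#' the grid electricity-vs-gas linear relation.
#'
#' @return Data frame with `year`, `electricity_usd_per_kwh`,
#'   `gas_usd_per_kcf`.
#' @export
default_energy_table <- function() {
  path <- system.file("extdata", "energy_prices_synthetic.csv",
                      package = "acbmcost", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' Selected electricity price
#'
#' The facility buys the cheapest available source: grid (linear in the
#' gas price), onsite boiler-turbine generation, and solar when enabled.
#'
#' @param gas_price Natural gas price, USD per 1000 cubic feet.
#' @param model An [energy_price_model()].
#' @return Price in USD/kWh.
#' @export
electricity_price <- function(gas_price, model) {
  if (any(gas_price < 0)) {
    stop("gas_price must be >= 0", call. = FALSE)
  }
  grid <- model$grid_slope * gas_price + model$grid_intercept
  onsite <- gas_price / (model$gas_energy_content * model$turbine_efficiency)
  price <- pmin(grid, onsite)
  if (isTRUE(model$solar_enabled)) price <- pmin(price, model$solar_cost)
  price
}

#' Annual process and wastewater cost
#'
#' Media volume is charged once as process water coming in and once as
#' wastewater (spent media) going out.
#'
#' @param media_annual_volume Annual media volume, L/yr.
#' @param process_rate Process water cost, USD/L.
#' @param wastewater_rate Wastewater treatment cost, USD/L.
#' @return Cost in USD/yr.
#' @export
water_costs <- function(media_annual_volume, process_rate, wastewater_rate) {
  stopifnot(all(media_annual_volume >= 0), all(process_rate >= 0),
            all(wastewater_rate >= 0))
  media_annual_volume * (process_rate + wastewater_rate)
}

#' Annual labor cost
#'
#' One laborer position per production bioreactor with continuous
#' around-the-clock coverage, costed by the factorial method:
#' `count * laborers * wage * hours * correction_factor`.
#'
#' @param bioreactor_count Number of production bioreactors.
#' @param wage Base wage, USD/h.
#' @param hours Covered hours per year.
#' @param correction_factor Factorial-method multiplier for supervision
#'   and overheads.
#' @param laborers_per_bioreactor Positions per bioreactor.
#' @return Cost in USD/yr.
#' @export
labor_cost <- function(bioreactor_count, wage, hours, correction_factor,
                       laborers_per_bioreactor = 1) {
  stopifnot(all(bioreactor_count >= 0), all(wage >= 0), all(hours >= 0),
            all(correction_factor >= 0), all(laborers_per_bioreactor >= 0))
  bioreactor_count * laborers_per_bioreactor * wage * hours *
    correction_factor
}

#' Annual fixed manufacturing cost
#'
#' Maintenance, insurance, property taxes and royalties estimated as a
#' fraction of the installed equipment cost.
#'
#' @param total_capex Installed capital, USD.
#' @param fraction Annual fraction in `[0, 1)`.
#' @return Cost in USD/yr.
#' @export
fixed_manufacturing_cost <- function(total_capex, fraction) {
  stopifnot(all(total_capex >= 0))
  if (any(fraction < 0 | fraction >= 1)) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  total_capex * fraction
}

#' Sum of the operating cost items
#'
#' @param costs An `acbm_operating_costs` object (or named list with the
#'   six items).
#' @return Total in USD/yr.
#' @export
total_operating <- function(costs) {
  items <- c("media", "oxygen", "energy", "water", "labor",
             "fixed_manufacturing")
  sum(unlist(costs[items]))
}

#' Itemized annual operating costs for a scenario
#'
#' Assembles media, oxygen, energy (heating, metabolic heat removal and
#' product chilling at the selected electricity price), water, labor and
#' fixed manufacturing into an itemized annual statement.
#'
#' @param params A validated `acbm_scenario`.
#' @param batch An [batch_plan()] (recomputed when omitted).
#' @param capital A [capital_plan()] (recomputed when omitted).
#' @param energy_model An [energy_price_model()] (default built from the
#'   packaged price table and the scenario's utility parameters).
#' @param charge_policy Media charge policy (see
#'   [media_volume_per_batch()]).
#' @return An object of class `acbm_operating_costs`.
#' @export
operating_costs <- function(params, batch = NULL, capital = NULL,
                            energy_model = NULL,
                            charge_policy = c("fractional", "ceiling")) {
  charge_policy <- match.arg(charge_policy)
  validate_scenario(params)
  if (is.null(batch)) batch <- batch_plan(params)
  if (is.null(capital)) capital <- capital_plan(params, batch)
  if (is.null(energy_model)) {
    energy_model <- energy_price_model(
      gas_energy_content = params$gas_energy_content,
      turbine_efficiency = params$turbine_efficiency,
      solar_enabled = params$solar_enabled)
  }
  wv_l <- params$bioreactor_working_volume * 1e3
  md <- media_volume_per_batch(batch$glucose_total,
                               params$glucose_concentration, wv_l,
                               charge_policy)
  annual_batches <- capital$batches_per_reactor_year *
    capital$bioreactor_count
  annual_volume <- md$volume_per_batch * annual_batches
  cost_l <- media_cost_per_liter(params$basal_media_cost,
                                 params$fgf2_concentration, params$fgf2_cost,
                                 params$tgfb_concentration, params$tgfb_cost)
  media <- annual_volume * cost_l

  oxygen_annual <- batch$oxygen_total * annual_batches
  oxygen <- oxygen_annual * params$oxygen_cost

  heat_kwh <- heating_energy(annual_volume, params$media_density,
                             params$media_specific_heat,
                             params$media_inlet_temperature,
                             params$culture_temperature) / 3600
  removal_kwh <- bioreactor_heat_removal(
    batch$metabolic_heat * annual_batches,
    params$heat_exchanger_efficiency) / 3600
  annual_mass <- batch$batch_mass * annual_batches
  cooling_kwh <- acbm_cooling_energy(annual_mass, params$acbm_specific_heat,
                                     params$acbm_outlet_temperature,
                                     params$acbm_chilled_temperature,
                                     params$heat_exchanger_efficiency) / 3600
  elec <- electricity_price(params$natural_gas_price, energy_model)
  energy <- (heat_kwh + removal_kwh + cooling_kwh) * elec

  water <- water_costs(annual_volume, params$process_water_cost,
                       params$wastewater_cost)
  labor <- labor_cost(capital$bioreactor_count, params$base_wage,
                      params$operating_hours_per_year,
                      params$labor_correction_factor,
                      params$laborers_per_bioreactor)
  fixed <- fixed_manufacturing_cost(capital$total_capex,
                                    params$fixed_manufacturing_fraction)
  out <- structure(list(
    media = media, oxygen = oxygen, energy = energy, water = water,
    labor = labor, fixed_manufacturing = fixed,
    media_demand = list(
      volume_per_batch = md$volume_per_batch,
      raw_volume_per_batch = md$raw_volume,
      charges_per_batch = md$charges,
      annual_volume = annual_volume,
      cost_per_liter = cost_l,
      annual_cost = media),
    electricity_price = elec,
    energy_kwh = heat_kwh + removal_kwh + cooling_kwh
  ), class = "acbm_operating_costs")
  out$total <- total_operating(out)
  out
}

#' @export
print.acbm_operating_costs <- function(x, ...) {
  cat("ACBM annual operating costs [USD/yr]\n")
  for (nm in c("media", "oxygen", "energy", "water", "labor",
               "fixed_manufacturing")) {
    cat(sprintf("  %-20s %14.4g\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-20s %14.4g\n", "total", x$total))
  cat(sprintf("  (media: %.4g L/yr at %.4g USD/L; electricity %.4g USD/kWh)\n",
              x$media_demand$annual_volume, x$media_demand$cost_per_liter,
              x$electricity_price))
  invisible(x)
}
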