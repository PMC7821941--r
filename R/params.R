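#' @keywords internal
"_PACKAGE"

# Canonical parameter registry. One row per scalar model input, grouped the
# way the process flow diagram groups them (operations, cellular, media,
# utility, labor, finance). `default` is the baseline-technology value
# (scenario 1); presets override a subset of rows.
#
# Units are embedded here once and propagated into every report header.
param_registry <- function() {
  row <- function(name, group, units, default, description) {
    data.frame(parameter = name, group = group, units = units,
               default = default, description = description,
               stringsAsFactors = FALSE)
  }
  rbind(
    ## -- operations ---------------------------------------------------------
    row("annual_production_mass", "operations", "kg/yr", 1.21e8,
        "target annual plant output (1% of US beef market)"),
    row("bioreactor_working_volume", "operations", "m3", 20,
        "working volume of one production bioreactor"),
    row("operating_hours_per_year", "operations", "h/yr", 8760,
        "annual operating hours (continuous operation)"),
    row("inoculum_fraction", "operations", "1", 0.01,
        "fraction of final cell number present at growth-phase start"),
    ## -- cellular attributes -------------------------------------------------
    row("cell_volume", "cellular", "m3/cell", 5e-15,
        "volume of a single myoblast/MSC"),
    row("cell_density", "cellular", "kg/m3", 1060,
        "density of eukaryotic muscle cells"),
    row("achievable_cell_concentration", "cellular", "cells/mL", 1.00e7,
        "cell concentration reached at end of growth phase"),
    row("hours_per_doubling", "cellular", "h", 24,
        "population doubling time during the growth phase"),
    row("maturation_time", "cellular", "h", 240,
        "post-growth differentiation/maturation period"),
    row("glucose_consumption_per_cell", "cellular", "mol/h/cell", 4.13e-13,
        "per-cell glucose uptake rate"),
    row("oxygen_uptake_per_cell", "cellular", "mol/h/cell", 2.478e-12,
        "per-cell oxygen uptake rate"),
    row("o2_steady_state_fraction", "cellular", "1", 0.02,
        "dissolved-oxygen set point maintained in the vessel"),
    ## -- media ---------------------------------------------------------------
    row("glucose_concentration", "media", "mol/L", 1.78e-2,
        "glucose concentration of the basal medium"),
    row("basal_media_cost", "media", "USD/L", 10.00,
        "medium cost per litre excluding FGF-2 and TGF-beta"),
    row("fgf2_concentration", "media", "g/L", 1.00e-4,
        "FGF-2 growth factor concentration"),
    row("fgf2_cost", "media", "USD/g", 2.05e6,
        "FGF-2 growth factor unit cost"),
    row("tgfb_concentration", "media", "g/L", 2.0e-6,
        "TGF-beta growth factor concentration"),
    row("tgfb_cost", "media", "USD/g", 8.09e7,
        "TGF-beta growth factor unit cost"),
    row("media_density", "media", "kg/L", 1.0,
        "medium density (approximately water)"),
    row("media_specific_heat", "media", "kJ/kg/degC", 4.184,
        "medium isochoric specific heat (approximately water)"),
    row("media_inlet_temperature", "media", "degC", 20,
        "temperature at which water/medium enters the facility"),
    row("culture_temperature", "media", "degC", 37,
        "culture temperature the medium is heated to"),
    ## -- utility -------------------------------------------------------------
    row("natural_gas_price", "utility", "USD/kcf", 6.40,
        "industrial natural gas price per 1000 cubic feet"),
    row("gas_energy_content", "utility", "kWh/kcf", 303.6,
        "potential energy of 1000 cubic feet of natural gas"),
    row("turbine_efficiency", "utility", "1", 0.35,
        "fuel-to-electricity efficiency of the onsite boiler-turbine"),
    row("process_water_cost", "utility", "USD/L", 2.6e-4,
        "process water supply cost"),
    row("wastewater_cost", "utility", "USD/L", 5.3e-4,
        "wastewater (spent media) treatment cost"),
    row("heat_exchanger_efficiency", "utility", "1", 0.9,
        "efficiency of the cooling/heat-exchange systems"),
    row("heat_per_mol_o2", "utility", "kJ/mol", 470,
        "metabolic heat released per mol O2 consumed"),
    row("acbm_specific_heat", "utility", "kJ/kg/degC", 2.24,
        "specific heat of the harvested product (as beef)"),
    row("acbm_outlet_temperature", "utility", "degC", 37,
        "product temperature leaving the bioreactor"),
    row("acbm_chilled_temperature", "utility", "degC", 4,
        "food-safety chilled storage temperature"),
    row("oxygen_cost", "utility", "USD/mol", 3.0e-3,
        "delivered industrial oxygen price"),
    row("oxygen_stoichiometry", "utility", "mol/mol", 6,
        "mol O2 per mol glucose under complete oxidation"),
    row("o2_molar_volume", "utility", "L/mol", 25.45,
        "molar volume of O2 gas at culture temperature"),
    ## -- labor ---------------------------------------------------------------
    row("base_wage", "labor", "USD/h", 13.68,
        "mean hourly wage for a meat packer"),
    row("labor_correction_factor", "labor", "1", 1.75,
        "factorial-method multiplier for supervision and overheads"),
    row("shifts_per_day", "labor", "count", 3,
        "number of 8-hour shifts covering continuous operation"),
    row("laborers_per_bioreactor", "labor", "count", 1,
        "laborer positions per full-scale bioreactor"),
    ## -- finance -------------------------------------------------------------
    row("equipment_unit_cost", "finance", "USD/m3", 50000,
        "food-grade bioreactor base cost per cubic metre"),
    row("scaling_exponent", "finance", "1", 0.6,
        "power-law equipment scaling exponent"),
    row("cepci_adjustment", "finance", "1", 1.29,
        "plant cost index inflation adjustment factor"),
    row("lang_factor", "finance", "1", 2,
        "installation/piping multiplier on purchased equipment"),
    row("debt_fraction", "finance", "1", 0.6,
        "fraction of capital financed by debt"),
    row("loan_interest_rate", "finance", "1/yr", 0.04,
        "interest rate on debt"),
    row("equity_interest_rate", "finance", "1/yr", 0.10,
        "required return on equity"),
    row("repayment_period", "finance", "yr", 30,
        "capital recovery period"),
    row("fixed_manufacturing_fraction", "finance", "1", 0.05,
        "annual fixed manufacturing cost as fraction of installed capital")
  )
}

# Non-numeric switches, kept outside the sensitivity-analysis vector.
param_switches <- function() {
  list(solar_enabled = FALSE)
}

#' Model parameter reference table
#'
#' Returns the registry of every scalar model input: its process-flow group,
#' units, baseline (scenario 1) default and a one-line description.
#'
#' @return A data.frame with columns `parameter`, `group`, `units`,
#'   `default`, `description`.
#' @export
#' @examples
#' head(acbm_parameters())
acbm_parameters <- function() {
  param_registry()
}

# Preset overrides relative to the baseline scenario. Scenario 2 is the
# mid-point technology scenario, scenario 3 removes FGF-2 cost from
# scenario 2, scenario 4 is the near-technical-limit bookend (growth
# factors eliminated, cheap basal medium, fast growth and maturation).
preset_overrides <- function() {
  list(
    scenario1 = list(),
    scenario2 = list(
      achievable_cell_concentration = 9.5e7,
      fgf2_concentration = 5.00e-5,
      fgf2_cost = 1.00e6,
      glucose_concentration = 2.67e-2,
      glucose_consumption_per_cell = 2.07e-13,
      hours_per_doubling = 16,
      maturation_time = 156
    ),
    scenario3 = list(
      achievable_cell_concentration = 9.5e7,
      fgf2_concentration = 5.00e-5,
      fgf2_cost = 0,
      glucose_concentration = 2.67e-2,
      glucose_consumption_per_cell = 2.07e-13,
      hours_per_doubling = 16,
      maturation_time = 156
    ),
    scenario4 = list(
      achievable_cell_concentration = 2.00e8,
      fgf2_concentration = 0,
      fgf2_cost = 0,
      glucose_concentration = 3.56e-2,
      glucose_consumption_per_cell = 4.13e-14,
      hours_per_doubling = 8,
      maturation_time = 24,
      tgfb_concentration = 0,
      tgfb_cost = 0,
      basal_media_cost = 0.24
    )
  )
}

#' Names of the packaged scenario presets
#' @return Character vector `"scenario1"` ... `"scenario4"`.
#' @export
scenario_names <- function() {
  names(preset_overrides())
}
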