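# Equipment costing and plant sizing.

#' Installed cost of one bioreactor
#'
#' Power-law ("six-tenths rule") equipment costing with a plant-cost-index
#' inflation adjustment and a Lang installation factor:
#' `unit_cost * volume^exponent * cepci_factor * lang_factor`.
#'
#' @param volume Vessel working volume, m3.
#' @param unit_cost Base cost per m3 (USD 50,000 for a food-grade vessel).
#' @param exponent Scaling exponent (0.6 conventionally).
#' @param cepci_factor Inflation adjustment from the cost-index ratio.
#' @param lang_factor Installation/piping multiplier.
#' @return Installed cost in USD.
#' @export
#' @examples
#' equipment_cost(20, 50000, 0.6, 1.29, 2)  # ~ USD 778,000
equipment_cost <- function(volume, unit_cost, exponent, cepci_factor,
                           lang_factor) {
  stopifnot(all(volume > 0), all(unit_cost > 0), all(exponent > 0),
            all(cepci_factor > 0), all(lang_factor > 0))
  unit_cost * volume^exponent * cepci_factor * lang_factor
}

#' Annual batches per bioreactor
#'
#' Semi-continuous operation with no downtime between batches:
#' `operating_hours / batch_time`, real-valued.
#'
#' @param operating_hours Operating hours per year.
#' @param batch_time Batch time in hours (> 0).
#' @return Batches per reactor-year.
#' @export
batches_per_year <- function(operating_hours, batch_time) {
  stopifnot(all(operating_hours >= 0))
  if (any(batch_time <= 0)) {
    stop("batch_time must be > 0", call. = FALSE)
  }
  operating_hours / batch_time
}

#' Number of production bioreactors required
#'
#' Demand divided by per-reactor annual throughput, rounded to the nearest
#' integer (minimum 1). Ceiling rounding is available for conservative
#' sizing.
#'
#' @param annual_production_mass Target annual output, kg.
#' @param batch_mass Mass per batch, kg.
#' @param batches_per_year Batches per reactor-year.
#' @param rounding `"nearest"` (default) or `"ceiling"`.
#' @return Integer-valued reactor count.
#' @export
bioreactors_required <- function(annual_production_mass, batch_mass,
                                 batches_per_year,
                                 rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  stopifnot(all(annual_production_mass >= 0))
  if (any(batch_mass * batches_per_year <= 0)) {
    stop("per-reactor annual throughput must be > 0", call. = FALSE)
  }
  x <- annual_production_mass / (batch_mass * batches_per_year)
  n <- if (rounding == "nearest") round(x) else ceiling(x)
  pmax(n, 1)
}

#' Capital plan for a scenario
#'
#' Sizes the plant (batches per reactor-year, reactor count) and costs the
#' production bioreactors; no other equipment is capitalized.
#'
#' @param params A validated `acbm_scenario`.
#' @param batch An [batch_plan()] for the same scenario (recomputed when
#'   omitted).
#' @param rounding Reactor-count rounding (see [bioreactors_required()]).
#' @return An object of class `acbm_capital_plan`.
#' @export
capital_plan <- function(params, batch = NULL,
                         rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  validate_scenario(params)
  if (is.null(batch)) batch <- batch_plan(params)
  bpy <- batches_per_year(params$operating_hours_per_year, batch$batch_time)
  n <- bioreactors_required(params$annual_production_mass, batch$batch_mass,
                            bpy, rounding)
  unit <- equipment_cost(params$bioreactor_working_volume,
                         params$equipment_unit_cost,
                         params$scaling_exponent,
                         params$cepci_adjustment,
                         params$lang_factor)
  structure(list(
    single_bioreactor_cost = unit,
    bioreactor_count = n,
    total_capex = unit * n,
    batches_per_reactor_year = bpy,
    annual_mass_per_reactor = batch$batch_mass * bpy
  ), class = "acbm_capital_plan")
}

#' @export
print.acbm_capital_plan <- function(x, ...) {
  cat("ACBM capital plan\n")
  cat(sprintf("  bioreactor installed cost [USD]: %.0f\n",
              x$single_bioreactor_cost))
  cat(sprintf("  bioreactors required:            %d\n", x$bioreactor_count))
  cat(sprintf("  batches per reactor-year:        %.2f\n",
              x$batches_per_reactor_year))
  cat(sprintf("  annual mass per reactor [kg/yr]: %.0f\n",
              x$annual_mass_per_reactor))
  cat(sprintf("  total capital [USD]:             %.4g\n", x$total_capex))
  invisible(x)
}
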