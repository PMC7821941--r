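# Cell-number kinetics and per-batch metabolic demand.
#
# Two cell trajectories are supported for the growth phase:
#   "stepwise"   N(t) = N0 * 2^floor(t / td)   (population doubles as a
#                discrete event at the end of every doubling period; the
#                default, and the form the packaged scenarios are
#                calibrated with)
#   "continuous" N(t) = N0 * 2^(t / td)        (smooth exponential)
# Integrals of rate * N(t) over the growth phase have closed forms for
# both; the continuous one is checked against numerical quadrature in the
# test suite.

#' Cell number at a given time
#'
#' @param initial_count Cells present at time zero.
#' @param doubling_time Hours per population doubling (> 0).
#' @param t Elapsed time in hours.
#' @param trajectory `"continuous"` (default) or `"stepwise"` doubling.
#' @return Cell count at time `t`.
#' @export
#' @examples
#' cells_at_time(1e12, 24, 72)  # three doublings
cells_at_time <- function(initial_count, doubling_time, t,
                          trajectory = c("continuous", "stepwise")) {
  trajectory <- match.arg(trajectory)
  stopifnot(all(initial_count >= 0), all(t >= 0))
  if (any(doubling_time <= 0)) {
    stop("doubling_time must be > 0", call. = FALSE)
  }
  if (trajectory == "continuous") {
    initial_count * 2^(t / doubling_time)
  } else {
    initial_count * 2^floor(t / doubling_time)
  }
}

#' Doublings in the growth phase
#'
#' The growth phase expands the inoculum to the final cell number, i.e.
#' `log2(1 / inoculum_fraction)` doublings.
#'
#' @param inoculum_fraction Fraction of the final cell number present at
#'   the start of the growth phase, in (0, 1).
#' @return Number of doublings (possibly fractional).
#' @export
growth_doublings <- function(inoculum_fraction) {
  stopifnot(all(inoculum_fraction > 0), all(inoculum_fraction < 1))
  log2(1 / inoculum_fraction)
}

#' Batch time
#'
#' Batch time is the sum of the cell growth phase and the maturation time.
#'
#' @param doubling_time Hours per doubling.
#' @param doublings Number of doublings in the growth phase.
#' @param maturation_time Maturation period in hours.
#' @return Batch time in hours.
#' @export
batch_time <- function(doubling_time, doublings, maturation_time) {
  stopifnot(all(doubling_time >= 0), all(doublings >= 0),
            all(maturation_time >= 0))
  doubling_time * doublings + maturation_time
}

#' Harvested mass of one batch
#'
#' Final cell count times single-cell volume times cell density. Errors if
#' the cells would occupy more than the working volume (packing bound);
#' equality — a fully packed vessel — is accepted.
#'
#' @param cell_concentration Final concentration in cells/mL.
#' @param working_volume Bioreactor working volume in m3.
#' @param cell_volume Single-cell volume in m3.
#' @param cell_density Cell density in kg/m3.
#' @return Batch mass in kg.
#' @export
#' @examples
#' batch_mass(1e7, 20, 5e-15, 1060)
batch_mass <- function(cell_concentration, working_volume, cell_volume,
                       cell_density) {
  stopifnot(all(cell_concentration >= 0), all(working_volume > 0),
            all(cell_volume >= 0), all(cell_density >= 0))
  frac <- cell_volume_fraction(cell_concentration, cell_volume)
  if (any(frac > 1 + 1e-12)) {
    stop("packing bound exceeded: total cell volume cannot exceed the ",
         "bioreactor operating capacity (volume fraction ",
         format(max(frac)), " > 1)", call. = FALSE)
  }
  cells <- cell_concentration * 1e6 * working_volume  # cells/mL -> cells/m3
  cells * cell_volume * cell_density
}

# Integral of N(t) dt over a growth phase of `doublings` doublings
# ("cell-hours" per unit initial count multiplied back by N0).
cell_hours_growth <- function(initial_count, doubling_time, doublings,
                              trajectory = c("stepwise", "continuous")) {
  trajectory <- match.arg(trajectory)
  if (trajectory == "continuous") {
    initial_count * (doubling_time / log(2)) * (2^doublings - 1)
  } else {
    k <- floor(doublings)
    initial_count * doubling_time * ((2^k - 1) + 2^k * (doublings - k))
  }
}

#' Glucose consumed during the growth phase
#'
#' Integrates the time-varying consumption `rate_per_cell * N(t)` over the
#' growth phase. For the continuous trajectory the closed form is
#' `r * N0 * (td / ln 2) * (2^(T/td) - 1)`; for the stepwise trajectory the
#' population is constant within each doubling period and the integral is
#' the corresponding finite sum (including a partial final period when
#' `T/td` is not an integer).
#'
#' @param rate_per_cell Glucose uptake in mol/h/cell.
#' @param initial_count Cells at the start of the growth phase.
#' @param doubling_time Hours per doubling (> 0).
#' @param duration Growth-phase length in hours.
#' @param trajectory `"stepwise"` (default) or `"continuous"`.
#' @return Glucose consumed in mol.
#' @export
glucose_growth_phase <- function(rate_per_cell, initial_count, doubling_time,
                                 duration,
                                 trajectory = c("stepwise", "continuous")) {
  trajectory <- match.arg(trajectory)
  stopifnot(all(rate_per_cell >= 0), all(initial_count >= 0),
            all(duration >= 0))
  if (any(doubling_time <= 0)) {
    stop("doubling_time must be > 0", call. = FALSE)
  }
  rate_per_cell *
    cell_hours_growth(initial_count, doubling_time, duration / doubling_time,
                      trajectory)
}

#' Glucose consumed during maturation
#'
#' The cell number is constant during maturation, so consumption is
#' `rate * final_count * maturation_time`.
#'
#' @param rate_per_cell Glucose uptake in mol/h/cell.
#' @param final_count Cells present throughout maturation.
#' @param maturation_time Maturation period in hours.
#' @return Glucose consumed in mol.
#' @export
glucose_maturation_phase <- function(rate_per_cell, final_count,
                                     maturation_time) {
  stopifnot(all(rate_per_cell >= 0), all(final_count >= 0),
            all(maturation_time >= 0))
  rate_per_cell * final_count * maturation_time
}

#' Oxygen equivalent of glucose oxidation
#'
#' Complete oxidation of glucose consumes 6 mol O2 per mol glucose.
#'
#' @param glucose_mol Glucose consumed, mol.
#' @param stoichiometry mol O2 per mol glucose (default 6).
#' @return Oxygen consumed, mol.
#' @export
oxygen_from_stoichiometry <- function(glucose_mol, stoichiometry = 6) {
  stopifnot(all(glucose_mol >= 0), all(stoichiometry >= 0))
  stoichiometry * glucose_mol
}

# Initial dissolved-oxygen charge to bring the vessel to the steady-state
# set point, treated as a gas volume fraction of the working volume.
initial_oxygen_charge <- function(working_volume_l, fraction, molar_volume) {
  fraction * working_volume_l / molar_volume
}

#' Per-batch oxygen demand
#'
#' The initial charge establishes the steady-state dissolved-oxygen set
#' point; consumption over the batch is either the per-cell uptake rate
#' integrated over the cell trajectory (default) or tied to glucose
#' oxidation stoichiometry.
#'
#' @param batch An [batch_plan()] object.
#' @param params The scenario the batch was computed from.
#' @param method `"per_cell"` (default) or `"stoichiometric"`.
#' @return List with `initial_charge`, `consumed` and `total` (mol).
#' @export
oxygen_demand <- function(batch, params,
                          method = c("per_cell", "stoichiometric")) {
  method <- match.arg(method)
  init <- initial_oxygen_charge(params$bioreactor_working_volume * 1e3,
                                params$o2_steady_state_fraction,
                                params$o2_molar_volume)
  consumed <- if (method == "per_cell") {
    params$oxygen_uptake_per_cell *
      (cell_hours_growth(batch$initial_cell_count, params$hours_per_doubling,
                         batch$doublings, batch$trajectory) +
         batch$final_cell_count * params$maturation_time)
  } else {
    oxygen_from_stoichiometry(batch$glucose_total,
                              params$oxygen_stoichiometry)
  }
  list(initial_charge = init, consumed = consumed, total = init + consumed)
}

#' Metabolic heat released
#'
#' @param oxygen_consumed Oxygen consumed, mol.
#' @param heat_per_mol_o2 Heat released per mol O2, kJ/mol (470 for glucose
#'   combustion).
#' @return Heat in kJ.
#' @export
metabolic_heat <- function(oxygen_consumed, heat_per_mol_o2) {
  stopifnot(all(oxygen_consumed >= 0), all(heat_per_mol_o2 >= 0))
  oxygen_consumed * heat_per_mol_o2
}

#' Per-batch growth and metabolism plan
#'
#' Derives every per-batch quantity from a scenario: cell counts, batch
#' time, harvested mass, glucose demand split by phase, oxygen demand and
#' metabolic heat.
#'
#' @param params A validated `acbm_scenario`.
#' @param trajectory Growth-phase cell trajectory (see
#'   [glucose_growth_phase()]).
#' @param oxygen_method Oxygen accounting (see [oxygen_demand()]).
#' @return An object of class `acbm_batch_plan`.
#' @export
#' @examples
#' batch_plan(scenario_preset("scenario1"))
batch_plan <- function(params, trajectory = c("stepwise", "continuous"),
                       oxygen_method = c("per_cell", "stoichiometric")) {
  trajectory <- match.arg(trajectory)
  oxygen_method <- match.arg(oxygen_method)
  validate_scenario(params)
  doublings <- growth_doublings(params$inoculum_fraction)
  growth_h <- doublings * params$hours_per_doubling
  bt <- batch_time(params$hours_per_doubling, doublings,
                   params$maturation_time)
  final_n <- params$achievable_cell_concentration * 1e6 *
    params$bioreactor_working_volume
  init_n <- final_n * params$inoculum_fraction
  mass <- batch_mass(params$achievable_cell_concentration,
                     params$bioreactor_working_volume,
                     params$cell_volume, params$cell_density)
  glc_g <- glucose_growth_phase(params$glucose_consumption_per_cell, init_n,
                                params$hours_per_doubling, growth_h,
                                trajectory)
  glc_m <- glucose_maturation_phase(params$glucose_consumption_per_cell,
                                    final_n, params$maturation_time)
  plan <- structure(list(
    initial_cell_count = init_n,
    final_cell_count = final_n,
    doublings = doublings,
    growth_phase_duration = growth_h,
    batch_time = bt,
    batch_mass = mass,
    glucose_growth = glc_g,
    glucose_maturation = glc_m,
    glucose_total = glc_g + glc_m,
    trajectory = trajectory,
    oxygen_method = oxygen_method
  ), class = "acbm_batch_plan")
  o2 <- oxygen_demand(plan, params, oxygen_method)
  plan$oxygen_initial_charge <- o2$initial_charge
  plan$oxygen_consumed <- o2$consumed
  plan$oxygen_total <- o2$total
  plan$metabolic_heat <- metabolic_heat(o2$consumed, params$heat_per_mol_o2)
  plan
}

#' @export
print.acbm_batch_plan <- function(x, ...) {
  cat("ACBM batch plan\n")
  cat(sprintf("  cells: %.4g -> %.4g (%.3f doublings, %s trajectory)\n",
              x$initial_cell_count, x$final_cell_count, x$doublings,
              x$trajectory))
  cat(sprintf("  batch time [h]:   %.2f (growth %.2f + maturation %.2f)\n",
              x$batch_time, x$growth_phase_duration,
              x$batch_time - x$growth_phase_duration))
  cat(sprintf("  batch mass [kg]:  %.1f\n", x$batch_mass))
  cat(sprintf("  glucose [mol]:    %.1f (growth %.1f + maturation %.1f)\n",
              x$glucose_total, x$glucose_growth, x$glucose_maturation))
  cat(sprintf("  oxygen [mol]:     %.1f (charge %.2f + consumed %.1f, %s)\n",
              x$oxygen_total, x$oxygen_initial_charge, x$oxygen_consumed,
              x$oxygen_method))
  cat(sprintf("  metabolic heat [kJ]: %.4g\n", x$metabolic_heat))
  invisible(x)
}
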