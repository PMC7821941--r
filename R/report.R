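# Reporting: published-reference comparison and report files.

#' Published reference values for the four scenarios
#'
#' The three headline outputs reported for each technology scenario:
#' required bioreactor count, annual media volume and minimum break-even
#' price.
#'
#' @return Data frame with `scenario`, `bioreactors`, `media_volume_l`,
#'   `min_price_usd_kg`.
#' @export
reference_outputs <- function() {
  data.frame(
    scenario = scenario_names(),
    bioreactors = c(5205, 360, 360, 50),
    media_volume_l = c(1.40e11, 3.06e10, 3.06e10, 8.56e8),
    min_price_usd_kg = c(4.37e5, 5.72e4, 4.46e4, 1.95),
    stringsAsFactors = FALSE
  )
}

#' Computed-versus-published comparison across the four scenarios
#'
#' Runs all four packaged presets and sets the computed bioreactor count,
#' annual media volume and minimum price beside the published reference
#' values, with signed relative deviations.
#'
#' @param ... Passed to [cost_breakdown()] (e.g. `charge_policy`).
#' @return Data frame, one row per scenario.
#' @export
#' @examples
#' scenario_comparison()
scenario_comparison <- function(...) {
  ref <- reference_outputs()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    b <- cost_breakdown(ref$scenario[i], ...)
    data.frame(
      scenario = ref$scenario[i],
      bioreactors = b$capital$bioreactor_count,
      bioreactors_ref = ref$bioreactors[i],
      media_volume_l_yr = b$operating$media_demand$annual_volume,
      media_volume_ref = ref$media_volume_l[i],
      media_volume_rel_dev =
        b$operating$media_demand$annual_volume / ref$media_volume_l[i] - 1,
      min_price_usd_kg = b$min_price,
      min_price_ref = ref$min_price_usd_kg[i],
      min_price_rel_dev = b$min_price / ref$min_price_usd_kg[i] - 1,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

breakdown_rows <- function(b) {
  data.frame(
    item = c("capital_total_usd", "annualized_capital_usd_yr",
             "operating_media_usd_yr", "operating_oxygen_usd_yr",
             "operating_energy_usd_yr", "operating_water_usd_yr",
             "operating_labor_usd_yr", "operating_fixed_manufacturing_usd_yr",
             "operating_total_usd_yr", "total_annual_usd_yr",
             "annual_mass_kg_yr", "min_price_usd_kg",
             "bioreactor_count", "batches_per_reactor_yr",
             "batch_mass_kg", "batch_time_h",
             "media_volume_l_yr", "media_cost_usd_l"),
    value = c(b$capital$total_capex, b$annualized_capital,
              b$operating$media, b$operating$oxygen, b$operating$energy,
              b$operating$water, b$operating$labor,
              b$operating$fixed_manufacturing, b$operating$total,
              b$total_annual, b$annual_mass, b$min_price,
              b$capital$bioreactor_count, b$capital$batches_per_reactor_year,
              b$batch$batch_mass, b$batch$batch_time,
              b$operating$media_demand$annual_volume,
              b$operating$media_demand$cost_per_liter),
    stringsAsFactors = FALSE
  )
}

breakdown_list <- function(b) {
  list(
    batch = b$batch[c("initial_cell_count", "final_cell_count", "doublings",
                      "growth_phase_duration", "batch_time", "batch_mass",
                      "glucose_growth", "glucose_maturation",
                      "glucose_total", "oxygen_total", "metabolic_heat")],
    capital = unclass(b$capital),
    operating = b$operating[c("media", "oxygen", "energy", "water", "labor",
                              "fixed_manufacturing", "total")],
    media_demand = b$operating$media_demand,
    annualized_capital = b$annualized_capital,
    total_annual = b$total_annual,
    annual_mass = b$annual_mass,
    min_price = b$min_price
  )
}

#' Write a scenario report to disk
#'
#' Emits, for one [cost_breakdown()], a CSV of the itemized costs (units
#' in the column values' row names), a JSON of the full breakdown, a CSV
#' echo of the input parameter vector, and a JSON run manifest listing
#' every artifact.
#'
#' @param b An `acbm_cost_breakdown`.
#' @param dir Output directory (created if needed).
#' @param scenario Label recorded in the manifest and file names.
#' @param seed Seed recorded in the manifest (NA when no randomness).
#' @param overrides Named list of overrides recorded in the manifest.
#' @return Manifest path, invisibly.
#' @export
write_report <- function(b, dir, scenario = "scenario", seed = NA,
                         overrides = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    costs = file.path(dir, paste0(scenario, "_costs.csv")),
    breakdown = file.path(dir, paste0(scenario, "_breakdown.json")),
    params = file.path(dir, paste0(scenario, "_parameters.csv"))
  )
  utils::write.csv(breakdown_rows(b), paths[["costs"]], row.names = FALSE)
  jsonlite::write_json(breakdown_list(b), paths[["breakdown"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  export_scenario_csv(b$params, paths[["params"]])
  manifest <- list(
    tool = "acbmcost",
    version = as.character(utils::packageVersion("acbmcost")),
    scenario = scenario,
    overrides = overrides,
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    artifacts = as.list(basename(paths))
  )
  manifest_path <- file.path(dir, paste0(scenario, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Write sensitivity-analysis outputs to disk
#'
#' Emits the normalized score matrix (parameters x algorithms) and the
#' raw matrix as CSV, the consensus set as JSON, and a manifest.
#'
#' @param res An `acbm_sensitivity` from [run_algorithms()].
#' @param dir Output directory.
#' @return Manifest path, invisibly.
#' @export
write_sensitivity <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  norm_path <- file.path(dir, "sensitivity_normalized.csv")
  raw_path <- file.path(dir, "sensitivity_raw.csv")
  cons_path <- file.path(dir, "sensitivity_consensus.json")
  utils::write.csv(data.frame(parameter = rownames(res$normalized),
                              res$normalized, check.names = FALSE),
                   norm_path, row.names = FALSE)
  utils::write.csv(data.frame(parameter = rownames(res$raw), res$raw,
                              check.names = FALSE),
                   raw_path, row.names = FALSE)
  jsonlite::write_json(
    list(k = res$k, seed = res$seed, consensus = res$consensus,
         top_k = res$top_k),
    cons_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    tool = "acbmcost",
    version = as.character(utils::packageVersion("acbmcost")),
    seed = res$seed,
    k = res$k,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    artifacts = list(basename(norm_path), basename(raw_path),
                     basename(cons_path))
  )
  manifest_path <- file.path(dir, "sensitivity_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
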