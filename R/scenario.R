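# Scenario construction, validation and (de)serialization.
#
# A scenario is a flat named list of scalar inputs carrying class
# "acbm_scenario". On disk it is a YAML document with one mapping per
# parameter group; unknown keys are an error so that typos in a large
# parameter space cannot pass silently.

#' Build a scenario parameter set
#'
#' Constructs a validated scenario from the baseline defaults plus any
#' overrides. `scenario_preset()` returns one of the four packaged
#' technology scenarios.
#'
#' @param ... Named scalar overrides (names must be registry parameters,
#'   see [acbm_parameters()]), or a single named list.
#' @return An object of class `acbm_scenario`: a named list of scalar
#'   parameter values plus the `solar_enabled` switch.
#' @export
#' @examples
#' p <- acbm_scenario(maturation_time = 120)
#' p$maturation_time
acbm_scenario <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  reg <- param_registry()
  p <- as.list(stats::setNames(reg$default, reg$parameter))
  p <- c(p, param_switches())
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; see acbm_parameters() for the valid set", call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  p <- structure(p, class = "acbm_scenario")
  validate_scenario(p)
  p
}

#' @rdname acbm_scenario
#' @param name Preset name, one of [scenario_names()].
#' @export
scenario_preset <- function(name) {
  presets <- preset_overrides()
  if (!name %in% names(presets)) {
    stop("unknown scenario preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  acbm_scenario(presets[[name]])
}

group_of <- function(parameter) {
  reg <- param_registry()
  g <- reg$group[match(parameter, reg$parameter)]
  ifelse(is.na(g), "switches", g)
}

#' Validate a scenario parameter set
#'
#' Checks completeness and the physical/financial invariants of the model:
#' non-negativity of all quantities, the cell packing bound (total cell
#' volume cannot exceed the bioreactor working volume), fraction ranges and
#' temperature orderings. Errors name the offending field and its group.
#'
#' @param p An `acbm_scenario` (or plain named list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_scenario <- function(p) {
  reg <- param_registry()
  required <- c(reg$parameter, names(param_switches()))
  missing <- setdiff(required, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ",
         paste(sprintf("%s (group %s)", missing, group_of(missing)),
               collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(p), required)
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (nm in reg$parameter) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter %s (group %s) must be a finite scalar",
                   nm, group_of(nm)), call. = FALSE)
    }
    if (v < 0) {
      stop(sprintf("invariant violated: %s (group %s) must satisfy %s >= 0",
                   nm, group_of(nm), nm), call. = FALSE)
    }
  }
  fail <- function(msg) stop("invariant violated: ", msg, call. = FALSE)
  frac <- cell_volume_fraction(p$achievable_cell_concentration, p$cell_volume)
  if (frac > 1 + 1e-12) {
    fail(paste0("achievable_cell_concentration x cell_volume <= 1 per unit ",
                "culture volume (total cell volume cannot exceed bioreactor ",
                "operating capacity); got volume fraction ",
                format(frac)))
  }
  if (!(p$inoculum_fraction > 0 && p$inoculum_fraction < 1)) {
    fail("0 < inoculum_fraction < 1")
  }
  if (p$debt_fraction > 1) fail("0 <= debt_fraction <= 1")
  if (!(p$heat_exchanger_efficiency > 0 && p$heat_exchanger_efficiency <= 1)) {
    fail("heat_exchanger_efficiency in (0, 1]")
  }
  if (!(p$turbine_efficiency > 0 && p$turbine_efficiency <= 1)) {
    fail("turbine_efficiency in (0, 1]")
  }
  if (p$acbm_chilled_temperature >= p$acbm_outlet_temperature) {
    fail("acbm_chilled_temperature < acbm_outlet_temperature")
  }
  if (p$media_inlet_temperature >= p$culture_temperature) {
    fail("media_inlet_temperature < culture_temperature")
  }
  for (nm in c("hours_per_doubling", "glucose_concentration",
               "bioreactor_working_volume", "operating_hours_per_year",
               "cell_density", "cell_volume", "repayment_period")) {
    if (p[[nm]] <= 0) {
      stop(sprintf("invariant violated: %s (group %s) must be > 0",
                   nm, group_of(nm)), call. = FALSE)
    }
  }
  if (!is.logical(p$solar_enabled) || length(p$solar_enabled) != 1L) {
    fail("solar_enabled must be a single logical")
  }
  invisible(p)
}

# Fraction of culture volume occupied by cells at the target concentration.
# concentration in cells/mL -> cells/m3 via 1e6.
cell_volume_fraction <- function(concentration, cell_volume) {
  concentration * 1e6 * cell_volume
}

#' Read a scenario from a YAML document or preset name
#'
#' `source` may be a preset name (`"scenario1"` ... `"scenario4"`, resolved
#' against the packaged fixture files) or a path to a YAML scenario document
#' with the six parameter groups. Fields omitted from the document default
#' to the baseline value; unknown keys are an error.
#'
#' @param source Preset name or file path.
#' @return A validated `acbm_scenario`.
#' @export
#' @examples
#' p <- load_scenario("scenario1")
#' p$achievable_cell_concentration
load_scenario <- function(source) {
  if (source %in% scenario_names()) {
    source <- system.file("extdata", "scenarios", paste0(source, ".yaml"),
                          package = "acbmcost", mustWork = TRUE)
  }
  if (!file.exists(source)) {
    stop("scenario source not found: ", source, call. = FALSE)
  }
  doc <- yaml::read_yaml(source)
  if (is.null(doc)) doc <- list()
  known_groups <- c(unique(param_registry()$group), "switches")
  bad_groups <- setdiff(names(doc), known_groups)
  if (length(bad_groups)) {
    stop("unknown parameter group(s) in ", source, ": ",
         paste(bad_groups, collapse = ", "), call. = FALSE)
  }
  known <- c(param_registry()$parameter, names(param_switches()))
  flat <- list()
  for (g in names(doc)) {
    entries <- doc[[g]]
    for (nm in names(entries)) {
      if (!nm %in% known) {
        stop("unknown parameter '", nm, "' in group '", g, "' of ", source,
             call. = FALSE)
      }
      actual <- group_of(nm)
      if (actual != g) {
        stop(sprintf("parameter %s listed under group '%s' but belongs to '%s'",
                     nm, g, actual), call. = FALSE)
      }
      flat[[nm]] <- entries[[nm]]
    }
  }
  acbm_scenario(flat)
}

#' Write a scenario to a YAML document
#'
#' The on-disk layout mirrors the process-flow grouping (operations,
#' cellular, media, utility, labor, finance, switches). Round-trips
#' losslessly: `load_scenario(write_scenario(p, f))` equals `p`.
#'
#' @param p A validated `acbm_scenario`.
#' @param destination File path to write.
#' @return `destination`, invisibly.
#' @export
write_scenario <- function(p, destination) {
  validate_scenario(p)
  reg <- param_registry()
  doc <- list()
  for (g in unique(reg$group)) {
    nms <- reg$parameter[reg$group == g]
    doc[[g]] <- p[nms]
  }
  doc[["switches"]] <- p[names(param_switches())]
  yaml::write_yaml(doc, destination, precision = 15L)
  invisible(destination)
}

#' Export the full parameter vector as CSV for audit
#'
#' One row per parameter with group, units and value.
#'
#' @param p A validated `acbm_scenario`.
#' @param destination CSV file path.
#' @return The audit data.frame, invisibly.
#' @export
export_scenario_csv <- function(p, destination) {
  validate_scenario(p)
  reg <- param_registry()
  out <- data.frame(parameter = reg$parameter, group = reg$group,
                    units = reg$units,
                    value = unlist(p[reg$parameter], use.names = FALSE))
  utils::write.csv(out, destination, row.names = FALSE)
  invisible(out)
}

#' @export
print.acbm_scenario <- function(x, ...) {
  reg <- param_registry()
  cat("ACBM scenario parameters\n")
  for (g in unique(reg$group)) {
    cat(sprintf("  %s:\n", g))
    for (nm in reg$parameter[reg$group == g]) {
      u <- reg$units[reg$parameter == nm]
      cat(sprintf("    %-32s %12.6g  [%s]\n", nm, x[[nm]], u))
    }
  }
  cat(sprintf("  switches:\n    %-32s %12s\n", "solar_enabled",
              x$solar_enabled))
  invisible(x)
}
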