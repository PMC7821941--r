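# Sensitivity analysis of the end-to-end price model.

#' Parameter bounds for the sensitivity analysis
#'
#' Builds the ranges each parameter is varied over. The default span is
#' half to twice the reference (baseline scenario) value, with physically
#' motivated clamps: fractions and efficiencies stay within their valid
#' ranges, temperatures vary by +/-10% so that orderings (inlet below
#' culture temperature, chilled below outlet) are preserved for every
#' sample, and the power-law exponent stays below 1.
#'
#' @param params Reference scenario the spans are anchored to.
#' @param span Multiplicative `c(lower, upper)` span (default `c(0.5, 2)`).
#' @return Object of class `acbm_bounds`: a data.frame with `parameter`,
#'   `group`, `lower`, `upper`.
#' @export
#' @examples
#' head(sensitivity_bounds())
sensitivity_bounds <- function(params = scenario_preset("scenario1"),
                               span = c(0.5, 2)) {
  validate_scenario(params)
  stopifnot(length(span) == 2, span[1] > 0, span[1] < 1, span[2] > 1)
  reg <- param_registry()
  v <- unlist(params[reg$parameter], use.names = FALSE)
  lower <- v * span[1]
  upper <- v * span[2]
  tweak <- function(b, nm, lo, hi) {
    i <- match(nm, reg$parameter)
    b$lower[i] <- lo; b$upper[i] <- hi
    b
  }
  b <- data.frame(parameter = reg$parameter, group = reg$group,
                  lower = lower, upper = upper, stringsAsFactors = FALSE)
  # fractions/efficiencies clamped to their valid range
  for (nm in c("debt_fraction", "heat_exchanger_efficiency",
               "turbine_efficiency")) {
    i <- match(nm, reg$parameter)
    b$upper[i] <- min(b$upper[i], 1)
  }
  i <- match("scaling_exponent", reg$parameter)
  b$upper[i] <- min(b$upper[i], 0.9)
  # temperatures: +/-10% keeps orderings valid for all samples
  for (nm in c("media_inlet_temperature", "culture_temperature",
               "acbm_outlet_temperature", "acbm_chilled_temperature")) {
    i <- match(nm, reg$parameter)
    b$lower[i] <- 0.9 * v[i]; b$upper[i] <- 1.1 * v[i]
  }
  if (any(b$lower >= b$upper)) {
    bad <- b$parameter[b$lower >= b$upper]
    stop("degenerate bounds (lower >= upper) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(b) <- c("acbm_bounds", "data.frame")
  b
}

#' Min-max normalization of the score matrix
#'
#' Each algorithm's column is scaled to `[0, 1]` by min-max; the DGSM
#' column is first compressed by its sixteenth root because its raw
#' magnitudes span many orders. A constant column (max equal to min) is
#' defined as all zero.
#'
#' @param raw Numeric matrix, parameters x algorithms, with column names.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
normalize_scores <- function(raw) {
  stopifnot(is.matrix(raw), !is.null(colnames(raw)), all(is.finite(raw)))
  out <- raw
  if ("DGSM" %in% colnames(out)) {
    x <- out[, "DGSM"]
    if (any(x < 0)) stop("DGSM scores must be >= 0", call. = FALSE)
    out[, "DGSM"] <- x^(1 / 16)
  }
  for (j in seq_len(ncol(out))) {
    rng <- range(out[, j])
    if (rng[2] > rng[1]) {
      out[, j] <- (out[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      out[, j] <- 0
      message("normalize_scores: constant column '", colnames(out)[j],
              "' set to zero")
    }
  }
  out
}

top_k_of <- function(scores, k) {
  ord <- order(-scores, seq_along(scores))  # score desc, canonical order
  names(scores)[ord[seq_len(k)]]
}

#' Cross-algorithm consensus parameter set
#'
#' The union, over algorithms, of each algorithm's `k` highest-scoring
#' parameters (raw scores; min-max scaling is monotone so the sets
#' coincide with the normalized ranking). Ties break deterministically by
#' score then canonical parameter order.
#'
#' @param result An `acbm_sensitivity` object (or raw score matrix).
#' @param k Parameters taken per algorithm.
#' @return Character vector of consensus parameters, in canonical
#'   (registry) order.
#' @export
consensus_top_k <- function(result, k = 5) {
  raw <- if (inherits(result, "acbm_sensitivity")) result$raw else result
  stopifnot(is.matrix(raw), !is.null(rownames(raw)))
  if (k < 1 || k > nrow(raw)) {
    stop("k must be between 1 and the number of parameters", call. = FALSE)
  }
  sets <- lapply(seq_len(ncol(raw)), function(j) top_k_of(raw[, j], k))
  members <- unique(unlist(sets))
  members[order(match(members, rownames(raw)))]
}

#' Run the six-algorithm sensitivity analysis
#'
#' Evaluates the end-to-end minimum-price model over the parameter bounds
#' with six global sensitivity algorithms (Sobol, Morris, FAST, RBD-FAST,
#' DGSM, delta moment-independent), min-max normalizes the scores for
#' presentation, and forms the per-algorithm top-`k` sets and their
#' consensus union. Fully reproducible under a fixed seed.
#'
#' @param bounds An [sensitivity_bounds()] object.
#' @param k Parameters taken per algorithm for the consensus.
#' @param seed Integer RNG seed.
#' @param base Scenario supplying non-registry context (energy model).
#' @param n_sobol,r_morris,n_fast,n_rbd,n_dgsm,n_dmim Per-algorithm sample
#'   sizes.
#' @return Object of class `acbm_sensitivity`: list with `raw` and
#'   `normalized` score matrices (parameters x algorithms), `top_k`
#'   per-algorithm sets, `consensus`, `k`, `seed`.
#' @export
run_algorithms <- function(bounds, k = 5, seed = 1,
                           base = scenario_preset("scenario1"),
                           n_sobol = 1024, r_morris = 100, n_fast = 1025,
                           n_rbd = 4096, n_dgsm = 512, n_dmim = 4096) {
  stopifnot(inherits(bounds, "acbm_bounds") || is.data.frame(bounds))
  if (any(bounds$lower >= bounds$upper)) {
    stop("bounds must satisfy lower < upper", call. = FALSE)
  }
  lower <- stats::setNames(bounds$lower, bounds$parameter)
  upper <- stats::setNames(bounds$upper, bounds$parameter)
  energy_model <- energy_price_model(
    gas_energy_content = base$gas_energy_content,
    turbine_efficiency = base$turbine_efficiency,
    solar_enabled = base$solar_enabled)
  model <- function(X) {
    colnames(X) <- names(lower)
    y <- evaluate_model_batch(X, base, energy_model)
    if (anyNA(y)) {
      stop("model returned NA prices inside the bounds; check bounds ",
           "against the scenario invariants", call. = FALSE)
    }
    as.numeric(y)
  }
  algos <- list(
    SSA = function() gsa_sobol(model, lower, upper, n = n_sobol),
    MM = function() gsa_morris(model, lower, upper, r = r_morris),
    FAST = function() gsa_fast(model, lower, upper, n = n_fast),
    "RBD-FAST" = function() gsa_rbdfast(model, lower, upper, n = n_rbd),
    DGSM = function() gsa_dgsm(model, lower, upper, n = n_dgsm),
    DMIM = function() gsa_dmim(model, lower, upper, n = n_dmim)
  )
  raw <- matrix(NA_real_, length(lower), length(algos),
                dimnames = list(names(lower), names(algos)))
  for (j in seq_along(algos)) {
    set.seed(seed + 1000L * j)
    raw[, j] <- algos[[j]]()
  }
  res <- structure(list(
    raw = raw,
    normalized = normalize_scores(raw),
    top_k = lapply(stats::setNames(colnames(raw), colnames(raw)),
                   function(a) top_k_of(raw[, a], k)),
    k = k,
    seed = seed
  ), class = "acbm_sensitivity")
  res$consensus <- consensus_top_k(res, k)
  res
}

#' @export
print.acbm_sensitivity <- function(x, ...) {
  cat(sprintf("ACBM sensitivity analysis (%d parameters x %d algorithms, seed %d)\n",
              nrow(x$raw), ncol(x$raw), x$seed))
  cat(sprintf("consensus of top-%d sets (%d parameters):\n", x$k,
              length(x$consensus)))
  for (p in x$consensus) cat("  -", p, "\n")
  invisible(x)
}
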