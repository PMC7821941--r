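# Capital annualization and the headline minimum price.

#' Capital recovery (annuity) payment
#'
#' Converts a capital sum into equal annual payments over `periods` years:
#' `principal * rate * (1+rate)^n / ((1+rate)^n - 1)`. The zero-rate limit
#' `principal / n` is handled analytically, and the formula is evaluated
#' through `log1p`/`expm1` so it stays accurate as `rate -> 0`.
#'
#' @param principal Capital sum, USD.
#' @param rate Annual interest rate (>= 0).
#' @param periods Repayment period in years (>= 1).
#' @return Annual payment, USD/yr.
#' @export
#' @examples
#' capital_recovery(1e6, 0.05, 10)
capital_recovery <- function(principal, rate, periods) {
  stopifnot(all(principal >= 0), all(rate >= 0))
  if (any(periods < 1)) {
    stop("periods must be >= 1", call. = FALSE)
  }
  n <- length(principal)
  m <- max(n, length(rate), length(periods))
  principal <- rep_len(principal, m)
  rate <- rep_len(rate, m)
  periods <- rep_len(periods, m)
  out <- numeric(m)
  zero <- rate == 0
  out[zero] <- principal[zero] / periods[zero]
  if (any(!zero)) {
    g <- periods[!zero] * log1p(rate[!zero])  # n * log(1 + i)
    out[!zero] <- principal[!zero] * rate[!zero] * exp(g) / expm1(g)
  }
  out
}

#' Annualized capital cost with a debt/equity split
#'
#' Debt and equity shares of the capital are each converted to annuities
#' at their own rate over the common repayment period.
#'
#' @param total_capex Installed capital, USD.
#' @param debt_fraction Fraction financed by debt, in `[0, 1]`.
#' @param loan_rate Interest rate on debt.
#' @param equity_rate Required return on equity.
#' @param periods Repayment period, years.
#' @return Annualized capital, USD/yr.
#' @export
annualize_capital <- function(total_capex, debt_fraction, loan_rate,
                              equity_rate, periods) {
  if (any(debt_fraction < 0 | debt_fraction > 1)) {
    stop("debt_fraction must be in [0, 1]", call. = FALSE)
  }
  capital_recovery(total_capex * debt_fraction, loan_rate, periods) +
    capital_recovery(total_capex * (1 - debt_fraction), equity_rate, periods)
}

#' Minimum break-even price
#'
#' The price per kilogram at which annual revenue exactly meets annualized
#' capital plus annual operating expenses.
#'
#' @param total_annual Total annual cost, USD/yr.
#' @param annual_mass Annual production, kg/yr (> 0).
#' @return Price in USD/kg.
#' @export
minimum_price <- function(total_annual, annual_mass) {
  if (any(annual_mass <= 0)) {
    stop("annual_mass must be > 0", call. = FALSE)
  }
  total_annual / annual_mass
}

#' Full cost breakdown for a scenario
#'
#' Runs the whole model for one scenario: batch plan, capital plan,
#' operating costs, capital annualization and the minimum price per kg.
#'
#' @param params A validated `acbm_scenario`, or a preset name.
#' @param energy_model Optional [energy_price_model()].
#' @param charge_policy Media charge policy (see
#'   [media_volume_per_batch()]).
#' @param trajectory Growth-phase cell trajectory (see
#'   [glucose_growth_phase()]).
#' @return An object of class `acbm_cost_breakdown` with elements
#'   `params`, `batch`, `capital`, `operating`, `annualized_capital`,
#'   `total_annual`, `annual_mass` and `min_price`.
#' @export
#' @examples
#' b <- cost_breakdown("scenario4")
#' b$min_price
cost_breakdown <- function(params, energy_model = NULL,
                           charge_policy = c("fractional", "ceiling"),
                           trajectory = c("stepwise", "continuous")) {
  charge_policy <- match.arg(charge_policy)
  trajectory <- match.arg(trajectory)
  if (is.character(params)) params <- load_scenario(params)
  validate_scenario(params)
  batch <- batch_plan(params, trajectory)
  capital <- capital_plan(params, batch)
  operating <- operating_costs(params, batch, capital, energy_model,
                               charge_policy)
  annualized <- annualize_capital(capital$total_capex, params$debt_fraction,
                                  params$loan_interest_rate,
                                  params$equity_interest_rate,
                                  params$repayment_period)
  annual_mass <- capital$annual_mass_per_reactor * capital$bioreactor_count
  total_annual <- annualized + operating$total
  structure(list(
    params = params,
    batch = batch,
    capital = capital,
    operating = operating,
    annualized_capital = annualized,
    total_annual = total_annual,
    annual_mass = annual_mass,
    min_price = minimum_price(total_annual, annual_mass)
  ), class = "acbm_cost_breakdown")
}

#' @export
print.acbm_cost_breakdown <- function(x, ...) {
  cat("ACBM cost breakdown\n")
  cat(sprintf("  total capital [USD]:        %.4g (%d bioreactors)\n",
              x$capital$total_capex, x$capital$bioreactor_count))
  cat(sprintf("  annualized capital [USD/yr]:%.4g\n", x$annualized_capital))
  cat(sprintf("  operating total [USD/yr]:   %.4g\n", x$operating$total))
  cat(sprintf("  annual mass [kg/yr]:        %.4g\n", x$annual_mass))
  cat(sprintf("  minimum price [USD/kg]:     %.4g\n", x$min_price))
  invisible(x)
}
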