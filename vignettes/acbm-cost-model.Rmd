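---
title: "The acbmcost model: assumptions, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The acbmcost model: assumptions, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acbmcost)
```

# What the model is

`acbmcost` estimates the minimum break-even price of animal cell-based
meat (ACBM) produced in a plant of stirred-tank bioreactors operating
semi-continuously, year-round, with no downtime for filling or
sanitation. It is deliberately a *minimum-cost* model: only the
production bioreactors are capitalized (no seed train, media storage,
oxygen supply, heat-exchange or spent-media equipment), operating costs
cover only media, oxygen, thermodynamic-minimum energy, water, direct
labor and fixed manufacturing charges, and indirect/overhead costs are
excluded. Reported prices should therefore be read as a floor under any
realistic plant, not a forecast.

A scenario is a flat vector of 48 scalar parameters grouped as
operations, cellular attributes, media, utility, labor and finance
(`acbm_parameters()` lists all of them with units). Four packaged
presets span a technology trajectory: scenario 1 is today's baseline
(10⁷ cells/mL, 376.80 USD/L medium rich in FGF-2 and TGF-β, 24 h
doubling, 240 h maturation); scenario 4 is the bookend in which nearly
every technical obstacle is resolved (2 × 10⁸ cells/mL — a fully packed
vessel — growth factors free, 0.24 USD/L medium, 8 h doubling, 24 h
maturation); scenarios 2 and 3 are mid-points, 3 differing from 2 only
by eliminating FGF-2 cost.

# Batch kinetics and the cell trajectory

A batch grows an inoculum `N0 = f · Nf` (inoculum fraction `f`, default
0.01) through `D = log2(1/f) ≈ 6.64` doublings and then matures at
constant cell number. Two trajectories for `N(t)` during growth are
implemented:

* **stepwise** (default): `N(t) = N0 · 2^floor(t/td)` — doubling as a
  discrete event at the end of each doubling period;
* **continuous**: `N(t) = N0 · 2^(t/td)` — smooth exponential growth.

Both give closed forms for the glucose integral `∫ r·N(t) dt`, and the
choice matters: over ~6.6 doublings the continuous integral is
`1/ln 2 ≈ 1.44` times larger per completed period. We ship stepwise as
the default because, jointly with `f = 0.01` and the fractional media
charge policy below, it reproduces the published reference outputs for
all four scenarios simultaneously — bioreactor counts exactly (5205 /
360 / 360 / 50) and annual media volumes within ±0.5% — whereas the
continuous trajectory overshoots media volumes by 3.5–9%. The continuous
form remains available (`trajectory = "continuous"`) and is the form
whose closed form is validated against numerical quadrature in the test
suite (its integrand is smooth, so a trapezoid oracle converges to
10⁻⁶ relative easily; the stepwise closed form is validated against an
independent per-period summation instead).

The inoculum fraction deserves emphasis: it is not printed as a primary
input anywhere in the reference outputs, but `f = 0.01` is the unique
round value for which the implied growth phase (`D · td`) makes the
published bioreactor counts come out exactly under nearest-integer
rounding (unrounded counts 5205.24 / 359.79 / 359.79 / 50.27). We treat
it as a calibrated constant and expose it as an ordinary parameter.

# Media accounting

Media volume per batch is driven entirely by glucose:
`V_raw = G_total / c_glucose`. Delivery is counted in *charges* of one
working volume (20,000 L). The charge count is fractional with a floor
of one charge — the initial vessel fill — rather than rounded up to
whole charges. Calibration against the published annual volumes decides
this: ceiling rounding inflates the bookend scenario's annual volume by
+6%, while fractional charges land within −0.5% on all four scenarios.
Users who want whole-charge logistics can set
`charge_policy = "ceiling"`; plant sizing and capital are unaffected
either way.

Media cost per litre is `basal + [FGF-2] · cost + [TGF-β] · cost`. The
packaged composition (basal 10.00 USD/L, FGF-2 10⁻⁴ g/L at
2.05 × 10⁶ USD/g, TGF-β 2 × 10⁻⁶ g/L at 8.09 × 10⁷ USD/g) reproduces the
published baseline total of 376.80 USD/L and the published FGF-2
contribution of 205 USD/L; scenario 4 zeroes the growth factors and uses
a 0.24 USD/L basal medium.

# Oxygen, heat and energy

Oxygen demand is the initial dissolved-oxygen charge to establish the 2%
set point (treated as a gas volume fraction of the working volume at the
culture-temperature molar volume, ≈16 mol for 20 m³ — negligible) plus
consumption, integrated over the same cell trajectory as glucose using a
per-cell uptake rate. The default rate, 2.478 × 10⁻¹² mol h⁻¹ cell⁻¹, is
six times the baseline glucose rate, i.e. the complete-oxidation
stoichiometry (6 mol O₂ per mol glucose); a purely stoichiometric mode
(`oxygen_method = "stoichiometric"`) ties oxygen to glucose directly and
serves as the cross-check in tests. Holding the oxygen rate fixed across
presets while the glucose rate falls is a simplification — it amounts to
assuming cells shift toward more oxidative metabolism as glucose demand
drops.

Each mol of O₂ consumed releases 470 kJ of metabolic heat, which must be
removed (charged at the heat-exchanger efficiency, default 0.9). Media
is heated from 20 °C to 37 °C (m·cp·ΔT, cp ≈ water); harvested product
is chilled from 37 °C to 4 °C at 2.24 kJ kg⁻¹ °C⁻¹ (beef). All three
terms are converted to kWh and priced at the cheapest available source:
grid electricity, modelled as a linear function of the industrial
natural gas price and refit by least squares at model-build time from
the packaged table `inst/extdata/energy_prices_synthetic.csv`
(package-constructed estimates of inflation-adjusted 1999–2019 national
industrial averages — labelled synthetic because they approximate, not
transcribe, a published series); onsite boiler–turbine generation,
priced as fuel cost over `303.6 kWh/kcf × turbine efficiency` (default
0.35); and solar at zero operating cost when explicitly enabled
(disabled by default, since treating operating cost as the only cost of
solar would zero the energy item entirely).

# Finance and remaining defaults

Capital is annualized as two annuities over a common repayment period:
the debt share at the loan rate and the equity share at the equity rate.
The capital recovery factor is evaluated via `log1p`/`expm1` so that the
zero-rate limit `P/n` is met to machine-level relative accuracy rather
than guarded by an epsilon, and `rate = 0` exactly returns `P/n`
analytically.

Several parameters have no published value in the reference outputs and
were fixed once from standard chemical-engineering costing practice;
they are deliberately constant across all four presets so that scenario
differences isolate technology:

| parameter | default | basis |
|---|---|---|
| debt fraction | 0.6 | typical project-finance gearing |
| loan / equity rate | 4% / 10% | investment-grade debt, modest equity hurdle |
| repayment period | 30 yr | plant lifetime |
| fixed manufacturing fraction | 5% of capital | maintenance + insurance + taxes |
| labor correction factor | 1.75 | supervision (~25%) + plant overheads (~50%) |
| oxygen price | 0.003 USD/mol | bulk industrial liquid oxygen |
| process / wastewater | 2.6 / 5.3 × 10⁻⁴ USD/L | municipal-scale industrial rates |
| heat-exchanger efficiency | 0.9 | well-designed utility systems |

Because media dominates operating cost in scenarios 1–3 by two or more
orders of magnitude, the headline prices are insensitive to these
choices; they matter most in scenario 4, where all non-media items
together contribute ≈0.3 USD/kg of the ≈2 USD/kg total.

# Plant sizing and numerical choices

Batches per reactor-year is real-valued (`8760 / t_batch`); the
bioreactor count is demand over per-reactor throughput rounded to the
*nearest* integer with a floor of one. Nearest (not ceiling) is chosen
because the published counts correspond to unrounded values of 5205.24
and 50.27; `rounding = "ceiling"` is available for conservative sizing.
The packing bound (cell volume fraction ≤ 1) accepts equality — scenario
4 sits exactly at 1.0, the model's physical limit — with a 10⁻¹²
relative tolerance against floating-point noise, and rejects anything
above. Degenerate inputs fail loudly: zero doubling time, zero glucose
concentration, zero annual mass and inverted temperature pairs are
errors, not NaNs.

# Sensitivity analysis

`run_algorithms()` evaluates the full pipeline (a vectorized twin of
`cost_breakdown()`, pinned to it by an equality test) under six global
sensitivity algorithms implemented in the package: Sobol first-order
indices (Saltelli estimator, 2¹⁰ base samples by default), Morris μ*
(100 trajectories, 4 levels), classic FAST (driving frequency per
parameter, 4 harmonics), RBD-FAST (single-frequency random balance
design with bias correction), DGSM (finite-difference mean squared
derivatives scaled by `(b−a)²/π²V`, the upper bound on the total
index), and the Borgonovo delta measure (equal-frequency conditioning
bins with kernel density estimates on a common grid). Estimator
correctness is validated against the analytic first-order indices of the
Ishigami function (0.3139, 0.4424, 0) and an inert-parameter property.
Each algorithm is seeded independently from the user seed, so a full run
is bit-reproducible. At the default sizes a six-algorithm run makes
roughly 1.8 × 10⁵ model evaluations and takes ~10 s on one CPU.

Scores are min–max normalized per algorithm for presentation; DGSM
values span many orders of magnitude and are compressed by a sixteenth
root before normalization. Top-k selection uses raw scores (min–max is
monotone, so the sets coincide) with deterministic ties broken by score
then canonical parameter order.

**Bounds, and a known limitation.** Default ranges are half to twice the
baseline value per parameter — a generic uncertainty band, clearly a
package choice, since no per-parameter ranges are published — with
clamps keeping fractions, efficiencies and the scaling exponent valid
and temperatures within ±10% so that every sampled row satisfies the
scenario invariants. Under these uniform relative bounds the price
model is close to a product of power functions, so all six algorithms
rank parameters near-identically: the same five (cell density, cell
volume, glucose concentration, glucose consumption rate, maturation
time) top every algorithm and the union of top-5 sets has exactly five
members, with the FGF-2 and TGF-β concentration/cost pairs ranked
6th–9th. Consensus *membership beyond the top five is therefore
range-sensitive*: bounds that reflect heterogeneous uncertainties (narrow
for physical cell constants, wide for costs) would promote the
growth-factor parameters into the top-5 sets and widen the union. The
bounds file mechanism (`read_bounds()`, the `--bounds` CLI option) exists
precisely so users can encode their own uncertainty structure; the
packaged default was fixed a priori and is not tuned to any expected
ranking.

# What the presets do and do not emulate

The presets encode the study conditions: a single plant sized to 1% of
the US beef market, 20 m³ vessels, year-round operation, and the four
technology levels above. Passing tests on these presets shows the
arithmetic chain — kinetics → demand → sizing → costing → price — is
faithful to the published scenario outputs. It does *not* validate the
model against a real plant: no contamination losses, no batch failures,
no downtime, no lactate/ammonia inhibition or Monod kinetics, no
scaffolding or downstream processing, no single-use systems, and
constant prices with no learning curves. The energy price table is a
constructed approximation, adequate because energy is ≪1% of cost in
every scenario.

# Problem sizes used in the packaged analyses

Scenario economics are closed-form and instant. The shipped analyses
use: Sobol 2¹⁰ base samples (≈51,200 evaluations over 48 parameters),
Morris 100 trajectories, FAST 1025 points per parameter, RBD-FAST 4096
samples, DGSM 512 base points, delta 4096 samples with 16 bins; the
Ishigami validation uses 8192 base samples. These sizes give stable
rankings across seeds for this model; all are arguments and can be
raised for harder response surfaces.
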