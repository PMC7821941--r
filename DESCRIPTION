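Package: acbmcost
Title: Techno-Economic Cost Model for Animal Cell-Based Meat Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scenario-based techno-economic model of animal cell-based meat
    (ACBM) production in stirred-tank bioreactors. From a vector of
    biological, engineering and financial input parameters the package
    computes per-batch cell growth and metabolic demands (glucose, oxygen,
    metabolic heat), sizes the bioreactor plant by power-law equipment
    costing with inflation and installation factors, itemizes annual
    operating expenditures (media, oxygen, energy, water, labor, fixed
    manufacturing), annualizes capital through debt and equity recovery,
    and reports the minimum break-even price per kilogram of product. Four
    technology-development scenario presets are packaged, and a global
    sensitivity analysis toolkit (Sobol, Morris, FAST, RBD-FAST, DGSM and
    delta moment-independent measures) ranks the most influential cost
    drivers with cross-algorithm consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
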