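Package: lakeghg
Title: Chamber-Based Greenhouse-Gas Flux Analysis for Thermokarst Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing floating-chamber greenhouse-gas surveys of
    thermokarst lakes: total CH4 and CO2 fluxes from chamber concentration
    time series, dissolved-gas concentrations and saturation from headspace
    equilibration samples, partitioning of CH4 emissions into diffusive and
    ebullitive components with a CO2-anchored two-layer gas-exchange model,
    stable-isotope classification of the methanogenic pathway and
    radiocarbon-age attribution, stratified Monte Carlo upscaling of lake
    fluxes to regional annual emissions, and the group-comparison statistics
    used throughout such surveys. Includes a synthetic-survey generator with
    known ground truth so every stage of the pipeline has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
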