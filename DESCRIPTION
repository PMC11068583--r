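Package: peatghg
Title: Greenhouse-Gas Flux Harmonization and Long-Term Carbon Budgets for
    Rewetted Peatlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for synthesizing greenhouse-gas flux measurements from
    rewetted boreal and temperate peatlands and for projecting long-term
    ecosystem carbon budgets under alternative land uses.  A curated flux
    compilation (net ecosystem exchange of CO2, CH4 and N2O across rewetted
    forests, paludiculture, shallow lakes and open bogs/fens) is shipped with
    per-study measurement units; a unit harmonizer converts the heterogeneous
    chamber and eddy-covariance unit dialects to canonical kg element per
    hectare per year; category-level balances are expressed in CO2
    equivalents under 100- and 500-year global-warming-potential horizons.
    An annual-step simulator projects peat and tree-stand carbon pools over
    centuries for pristine, drained and restored ombrotrophic peatland
    scenarios, including stem-volume increment schedules, fixed allometric
    partitioning to branches and coarse roots, 100-year harvest rotations,
    and trajectory diagnostics such as the carbon-neutrality year.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
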