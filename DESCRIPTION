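Package: silvharm
Title: Harmonization of Heterogeneous Forest-Simulation Outputs into
    Discrete Vegetation States with Standardized Climate and Soil Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts annual outputs of process-based forest simulation
    models (species basal-area shares, canopy height statistics, leaf area
    index) into canonical discrete vegetation-state strings, harmonizes
    heterogeneous height statistics to dominant stand height via allometric
    factors and linear mixed models, matches each simulation to the
    best-fitting daily climate trajectory from a scenario catalogue
    (trajectory selection by temperature and precipitation trend slopes,
    mean-level adjustment, year-by-year matching with randomized sampling
    among the three best years), completes quantitative soil vectors
    including plant-available nitrogen estimated through a
    pseudo-mineralization generalized linear model, stratifies climate and
    soil space into discrete bins and computes area coverage, and writes
    per-scenario SQLite databases with a wide daily-climate schema.
    Ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable without external gridded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    lme4,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
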