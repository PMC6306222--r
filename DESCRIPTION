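Package: envtraj
Title: Climate-Envelope Modelling and Ensemble Trajectory Analysis for
    Categorical Vegetation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits ensemble-of-trees climate envelope models of categorical
    vegetation on gridded bioclimatic surfaces and forecasts them under
    multiple scenario-by-time-step climates (GCM x RCP). Provides majority-area
    rescaling of fine categorical maps to climate-cell resolution with
    co-occurrence statistics, per-cell relative-likelihood averaging across
    scenario outputs, argmax and legacy-persistence assignment rules, ensemble
    agreement, diversity and temporal-stability maps, per-class area
    trajectories with trend classification, and regional and
    climate-by-vegetation summary tables. Includes a synthetic-landscape
    generator with known niche structure so the whole pipeline is testable
    end-to-end, plain-text raster and score-table I/O, a YAML-configured
    pipeline driver, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
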