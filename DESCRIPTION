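Package: nichebam
Title: Ensemble Niche Models and BAM Set Theory for Symbiont-Host Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates climatically suitable areas for a symbiont (A) and the
    availability area of its host (B) with an ensemble of eight species
    distribution modelling algorithms, combines the binarised consensus maps
    by raster set algebra into climate-limited (BI) and host-limited (G_BI)
    zones, and diagnoses which of the three possible BAM (biotic-abiotic-
    movement) interaction configurations holds.  Includes a virtual-species
    simulator with known ground truth so the full workflow can be validated
    end to end: spatially autocorrelated climate predictors, parametric
    niche responses, suitability-proportional occurrence sampling, and a
    controllable true BAM case.  Raster handling uses a lightweight in-memory
    grid on a regular lon/lat lattice with ESRI ASCII grid input/output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    MASS,
    mgcv,
    nnet,
    rpart,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
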