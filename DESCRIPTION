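Package: synergyci
Title: Median-Effect, Combination-Index and Independence-Model Analysis of
    Fixed-Ratio Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies drug-combination synergy from plate-reader viability
    data using the median-effect (mass-action) model and the Combination
    Index, with Bliss Independence and Highest Single Agent reference models
    for cross-validation. Fits four-parameter logistic dose-response curves
    and absolute IC50s, computes dose-reduction indices and Fa-CI curves for
    fixed-ratio designs, and summarises redox and apoptosis marker panels
    (fold change, percent of control, Annexin/PI quadrant totals, 2^-ddCt
    relative expression). A seedable simulator generates well-level
    combination screens, marker panels and Ct tables with known ground truth
    under Loewe-additive, Bliss-independent or potency-shifted interaction
    so that every analysis stage is testable end to end. Ships a worked
    quercetin + gemcitabine example in MDA-MB-231 cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
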