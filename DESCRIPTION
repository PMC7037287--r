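Package: grapetrace
Title: Heavy-Metal Biomonitoring in the Soil-Grapevine-Wine System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for element biomonitoring of vineyards around
    point pollution sources. Loads tidy concentration tables for soil (four
    depths), grapevine organs (roots, canes, leaves, grapes), must and wine;
    grades soil against tiered regulatory thresholds (normal, alert and
    intervention by land-use susceptibility) and beverages against maximum
    permissible limits; computes translocation factors and mobility ratios
    along the soil-root-cane-leaf/grape-must-wine chain with accumulator,
    indicator or excluder classification and element rankings; provides
    Pearson correlation matrices with significance stars, one-way ANOVA with
    Duncan multiple-range compact letter displays, linear discriminant
    analysis of geographic origin with cross-validation, and hierarchical
    clustering of element profiles with Newick export. Includes
    calibration-curve detection and quantification limits, recovery checks,
    and a synthetic-data generator emulating a distance-decaying pollution
    gradient with compartment partitioning, lognormal replicate noise and
    left-censoring at the limit of quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    ape,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
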