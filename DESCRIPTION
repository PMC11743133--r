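Package: thermofoot
Title: Thermodynamic Life-History Optimisation and Agricultural Footprint
    Estimation for Insect Pests
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling thermal adaptation of ectotherm pests and its
    agricultural consequences. Implements a thermodynamic life-history model in
    which juvenile resource acquisition (M) and allocation fractions to
    catalytic capacity (p) and cellular maintenance (q) are optimised against
    Arrhenius-type productivity kinetics and protein-stability failure;
    thermal performance and impact curves for adapted strategies; agricultural
    footprint metrics built from life-history traits and host-consumption
    conversion constants, with parametric bootstrap confidence intervals;
    host-consumption regression estimators; post-differential-expression
    analytics of reproduction/maintenance trade-off gene sets (overlap
    statistics, antagonistic classification, trade-off scores, eigen-axis
    projection); and deterministic synthetic-data generators emulating a
    three-origin, two-regime experimental-evolution design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
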