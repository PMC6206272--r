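Package: chemovar
Title: Cannabinoid Chemotyping from Targeted LC-MS Peak Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the twelve major phytocannabinoids from LC-MS
    selected-ion-monitoring peak areas via quadratic calibration curves,
    converts neutral cannabinoids to acid equivalents using
    molecular-weight decarboxylation factors, and computes the alkyl
    (C3/C5) and ring-type (dicyclic/tricyclic) chemotype fraction
    statistics for Cannabis diversity panels. Includes through-origin
    regression with stepwise standardized-residual deletion for assessing
    developmental stability of chemotype, k-means categorization of
    chemotypes across developmental stages with an elbow criterion, and a
    synthetic panel generator that emulates a 99-plant, 20-accession
    diversity collection segregating at a codominant B locus, down to
    calibration standards and duplicate-extract peak areas, so the whole
    pipeline can be exercised end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
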