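Package: flapqsar
Title: Alignment-Independent 3D-QSAR and Activity Profiling of FLAP Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for probing structure-activity profiles of
    5-lipoxygenase-activating protein (FLAP) inhibitors: activity curation
    with lipophilic efficiency (LipE) filtering, descriptor filtering and
    recursive feature elimination with classification metrics, common-scaffold
    clustering of docked poses by RMSD, GRID-like molecular interaction
    fields for DRY/O/N1/TIP probes, alignment-independent correlogram
    (GRIND-style) descriptor encoding, and partial least squares regression
    with leave-one-out cross-validation, fractional factorial design variable
    selection, and rm2 validation metrics. Includes synthetic-data generators
    that plant known pharmacophore geometry, pose-cluster structure, and
    informative descriptor columns so that every stage of the pipeline can be
    tested against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
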