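Package: vmatqa
Title: Aperture Complexity Analysis for VMAT Plan Quality Assurance
Version: 0.1.0
Authors@R:
    person("vmatqa", "maintainers", email = "vmatqa@example.org",
           role = c("aut", "cre"))
Description: Scores volumetric-modulated arc therapy (VMAT) treatment plans
    with an aperture complexity metric: the monitor-unit-weighted mean of the
    side perimeter to open area ratio (y/A, units 1/mm) over all control-point
    apertures. Reads DICOM-RT Plan files, reconstructs multileaf-collimator
    apertures, aggregates per-control-point, per-arc and per-plan complexity,
    compares a plan against a reference cohort (histogram, percentile,
    site-stratified summary tables), and calibrates a pass/fail QA-prediction
    threshold by receiver operating characteristic (ROC) analysis under a
    false-positive-rate constraint. Includes generators for synthetic RTPLAN
    fixtures with controllable modulation and for labeled synthetic cohorts,
    plus a command-line interface suitable for gating a planning workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
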