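Package: fdgclamp
Title: Tissue Glucose Uptake and Insulin Sensitivity from FDG-PET Clamp Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for [18F]fluorodeoxyglucose (FDG)
    positron emission tomography performed during a hyperinsulinemic-
    euglycemic clamp. Estimates the tracer influx constant Ki by
    Patlak-Gjedde graphical analysis or its fractional uptake rate (FUR)
    approximation from regional time-activity curves and a hybrid
    image-derived plus arterialized-plasma input function, converts rates
    to tissue and depot glucose uptake via lumped constants, and derives
    whole-body indices (M value, tracer-based rate of disappearance,
    endogenous glucose production, free fatty acid suppression,
    Matsuda insulin sensitivity index, HbA1c unit conversion). Includes a
    synthetic-data generator (two-tissue irreversible compartment model,
    frame-schedule binning, clamp records, two-group cohorts) and a
    cohort statistics layer with two-group tests, age adjustment,
    correlation analysis, Benjamini-Hochberg false discovery rate control
    and a simplified voxelwise group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
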