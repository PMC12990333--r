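Package: ervquant
Title: Pixel-Based Quantification of the Extent of Retinal Vascularization
    in Retinopathy of Prematurity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the nasal and temporal extent of retinal
    vascularization (NERV/TERV) in retinopathy of prematurity fundus
    imaging from manually clicked ridge (stage) points. Unordered clicks
    are ordered by a multi-start greedy nearest-neighbour traversal,
    smoothed by interpolating parametric splines, resampled at pixel
    resolution, and converted to radial distance profiles from the
    optic-disc centroid, yielding per-image minimum and mean ERV, the
    meridian angle of the minimum, and notch phenotypes. Includes the
    cohort statistics used to characterise these measurements (zone
    discrimination via Mann-Whitney AUROC, paired nasal-temporal
    asymmetry, ICC(2,1) intergrader reproducibility, stage-stratified
    vascular severity comparisons with Holm adjustment) and a calibrated
    synthetic-cohort generator so that the whole annotation-to-statistics
    pipeline can be exercised and validated without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
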