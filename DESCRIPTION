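Package: aortacalc
Title: Extended Thoracic Aorta Calcium Scoring on Non-Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify thoracic aorta calcium (TAC) over the full
    thoracic aorta, including the aortic arch that routine coronary calcium
    scans leave out. Provides synthetic CT phantom and cohort generators with
    analytic ground truth, semiautomatic aortic centerline extraction by
    inscribed-circle tracking over axial and oblique (semitoroidal) planes,
    landmark-based partition of the vessel into five anatomical segments,
    per-lesion Agatston scoring with segment assignment, and cohort-level
    statistics contrasting standard (ascending + distal descending) against
    extended (all five segments) TAC assessment, including reclassification
    group analysis and Framingham risk comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
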