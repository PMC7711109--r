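Package: mindstates
Title: Individualized Decoding of Internal Attention States from fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-subject multi-voxel pattern analysis of internal attention.
    Trains L2-penalized multinomial logistic classifiers on block-designed
    internal-attention fMRI data (attention to breath, feet, mind wandering,
    self-referential processing, and ambient sounds), validates them with
    leave-one-block-out cross-validation and chi-square tests against chance,
    derives classifier importance maps and group frequency maps, decodes a
    breath-focused meditation period TR by TR, segments decoded decisions into
    mental events, and summarizes each session as attention metrics (percentage
    time per state, event counts, event durations). Includes a synthetic
    session generator with known ground truth so the full pipeline can be
    exercised and validated without scanner data, and demographic
    dual-reporting summaries for cohort description.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
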