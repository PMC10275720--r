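Package: dbsmap
Title: Mapping Deep Brain Stimulation Outcomes to Stimulation Sites and
    Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-wise mapping of deep brain stimulation (DBS) outcomes
    in a patient cohort. Models stimulation volumes by thresholding a
    simplified electric field at 0.2 V/mm, fits an improvement-weighted
    voxel-wise t-score sweetspot model (T-model) with coverage gating and
    permutation validation, assembles a normative resting-state fMRI
    connectome (motion QC by framewise displacement, motion and nuisance
    regression, spatial smoothing, band-pass filtering), and maps the
    whole-brain network associated with clinical improvement via
    seed-based connectivity fingerprints and a voxel-wise R-map. Ships a
    synthetic-data generator with planted ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
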