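Package: visuomotor
Title: Visuomotor Association Learning: Behavior Statistics, Widefield
    Imaging, and Unit Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for a head-fixed mouse visuomotor wheel task
    studied with widefield calcium imaging and Neuropixels recordings.
    Implements a conditional-randomization test for stimulus-movement
    association against reaction-time null distributions replayed from the
    task's inter-trial-interval and quiescence timer logic; a widefield
    fluorescence processing chain (SVD compression, dual-wavelength
    hemodynamic correction, dF/F normalization, kernel deconvolution,
    master-basis recasting, rigid vasculature alignment, movement-weighted
    hemisphere subtraction, and retinotopic visual field sign mapping); and
    electrophysiology utilities (seven-criterion unit quality control,
    refractory-period contamination estimation, amplitude-truncation
    missingness, surface-channel detection, multiunit normalization, and a
    within-trial shuffle test of stimulus/movement responsiveness).
    Synthetic session, widefield, retinotopy and spike-train generators with
    known ground truth make every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
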