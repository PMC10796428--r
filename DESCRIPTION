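Package: seizr
Title: Signal Processing for Chemogenetic Seizure-Control Electrophysiology and Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for chemogenetic epilepsy experiments:
    EEG seizure detection by interictal-spike clustering with duration gating,
    electrically evoked seizure-threshold determination, hippocampal
    oscillation and sharp-wave-ripple analysis, patch-clamp
    intrinsic-excitability metrics, Hill dose-response fitting, fluorescence
    DF/F trace analysis with a permutation null for seizure-coupled responses,
    and treatment-effect quantification on seizure timelines. Includes a
    synthetic-data generator that plants ground-truth events in every input
    modality so all stages are testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
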