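Package: preictal
Title: Seizure Advisory Algorithms for Chronic Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and evaluating patient-specific seizure
    advisory algorithms on chronic multichannel intracranial EEG. Provides a
    synthetic long-duration iEEG generator with seizure events, pre-ictal
    signatures, antiepileptic-drug confounds and unreliable patient diaries; a
    channel-by-filter-by-analyzer feature bank (288 features for 16 channels);
    per-patient training by forward selection and backward elimination under
    block-wise cross-validation; a red/white/blue advisory state machine with
    trial event-handling rules (cluster collapsing, eligibility screening,
    leading seizures); chance-predictor-corrected performance statistics
    (sensitivity above chance at matched time under warning, blue-state false
    negative rate and negative predictive value, likelihood ratios); and a
    packaged first-in-man trial summary table with recomputation of its
    derived quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    parallel,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
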