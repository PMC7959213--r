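Package: cbloop
Title: Simulation of a Closed-Loop ssVEP Brain-Computer Interface with
    Deceptive Feedback
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse a closed-loop
    electroencephalography (EEG) brain-computer interface experiment in
    which introspective reports are probed with occasionally deceptive
    feedback.  The package generates synthetic 64-channel steady-state
    visually evoked potential (ssVEP) EEG from phase-opposed 1.875 Hz
    stimulus drives, implements the online preprocessing chain
    (downsampling, one-pass Butterworth band-pass, average reference),
    trains lagged backward stimulus-reconstruction models by ridge
    regression, streams windowed correlation scores and decodes the
    attended stimulus, schedules informative/deceptive feedback sessions,
    computes trial-level internal-evidence and bootstrap consistency
    indices, models reports and 4-level confidence with a
    reliability-weighted cue-integration observer, and reproduces the
    summary analyses (accuracy by feedback type, confidence median split,
    percentile-binned curves, and a fixed-effects logistic regression).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
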