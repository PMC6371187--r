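Package: brainload
Title: Simulated EEG Brain-Workload (Theta/Alpha Ratio) Analysis for
    Pre-Post Inhibition-Task Training Studies
Version: 0.1.0
Authors@R:
    person("J.", "Keller", email = "jkeller@example.org",
           role = c("aut", "cre"))
Description: Tools to generate the trial sequences of three classic
    response-inhibition paradigms (color-word Stroop, letter negative
    priming, arrow flanker), to simulate behavioral responses and
    continuous multi-channel EEG for three-group pre/post training
    cohorts, and to analyze the resulting data with the frontal-theta /
    parietal-alpha brain-workload score (TAR = theta power at Fz divided
    by alpha power at Pz, from stimulus-locked 2-s epochs of correct,
    artifact-free trials) together with planned orthogonal-contrast
    regression of pre-post training gains and repeated-measures effect
    sizes corrected for the dependence between means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
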