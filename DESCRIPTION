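Package: trirove
Title: Simulation and Analysis of Tri-Modal Roving-Oddball fMRI Experiments
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cross-modally conditioned roving-oddball designs in
    fMRI. Builds the 8-state Markov transition model that couples auditory,
    somatosensory and visual intensity sequences, samples tolerance-validated
    stimulus runs with a minimum-repetition constraint, annotates trials
    (standard/deviant roles, train lengths, cross-modal predictability),
    generates synthetic region-level BOLD data with configurable ground-truth
    effects and AR(1)+drift noise, and analyses them with first-level GLMs
    (parametric modulators and train-length bins), second-level tests,
    minimum-statistic conjunction against the global null, and seed-based
    psychophysiological-interaction (PPI) connectivity estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
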