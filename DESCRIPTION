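Package: fetalqc
Title: Motion-Artifact Quality Control for Fetal Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-level detection of motion-corrupted functional
    connectivity in fetal resting-state fMRI. Computes sliding-window
    time-varying functional connectivity and window-averaged framewise
    displacement, tests their association against parametric and
    phase-randomization surrogate nulls, and benchmarks nuisance-regression
    strategies (head-motion parameter expansions, tissue regressors, global
    signal regression, aCompCor, tCompCor, local white matter) at subject
    and group level, including the classical QC-FC metric. Ships a
    parametric generative model of corrupted BOLD signal pairs with known
    neural ground truth (hidden-Markov neural events, double-gamma
    hemodynamic response, episodic shared physiological noise, thermal
    noise) for validating quality-control procedures, framewise
    displacement from six rigid-body realignment parameters with
    per-subject brain-sphere estimation, and intensity/FD-based censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
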