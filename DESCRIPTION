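Package: pactacs
Title: Tailored tACS Waveforms and Occipital Alpha-Gamma Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transcranial alternating current stimulation
    (tACS) with gamma bursts entrained on a specific phase of the alpha cycle,
    and its effect on dynamic visual acuity (DVA). Synthesizes peak-, trough-
    and sham-condition injection-current waveforms with phase-locked 80 Hz
    bursts riding on a 10 Hz carrier; generates the 4-alternative forced-choice
    DVA trial schedule and scores behavior; simulates occipital EEG with 1/f
    background, alpha rhythm, phase-amplitude-coupled gamma, artifacts and EOG
    saccades; computes inter-trial phase coherence (Morlet wavelets), power
    spectra and Tort modulation-index comodulograms on pre-stimulus epochs;
    and runs the nonparametric statistical plan (Friedman omnibus, Wilcoxon
    signed-rank post-hocs, Benjamini-Hochberg FDR) over a simulated cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
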