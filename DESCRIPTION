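Package: qeegband
Title: Quantitative EEG Band Amplitude Profiling for Eyes-Closed Resting Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative electroencephalography (QEEG) of
    eyes-closed resting-state recordings on the nine-lead 10-20 montage
    (Fz F3 F4 Cz C3 C4 Pz P3 P4). Reads and writes EDF, re-references to
    the Fz/Cz/Pz midline, segments fixed-length analysis epochs, removes
    ocular, cardiac and muscular artifacts by blind source separation
    (FastICA), quantifies per-band peak-to-peak amplitudes (Delta, Theta,
    Alpha, SMR, Beta1, Beta2) from constrained FFT amplitude-spectrum
    peaks, classifies amplitudes against adult normative ceilings, scores
    inter-hemispheric asymmetry, and runs region-wise repeated-measures
    ANOVA with partial eta-squared and assumption checks. A synthetic-EEG
    cohort generator with injectable artifacts and known band-amplitude
    ground truth makes every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    signal,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
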