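Package: fpvs
Title: Frequency-Tagging (FPVS) EEG Analysis of Facial Expression Discrimination
Version: 0.1.0
Authors@R: person("FPVS", "Maintainers", email = "fpvs@example.org", role = c("aut", "cre"))
Description: Tools for fast periodic visual stimulation (FPVS) EEG experiments
    in which neutral faces are presented at a 6 Hz base rate and expressive
    faces at every fifth position (1.2 Hz oddball rate). Implements
    frequency-domain quantification of base and expression-change responses
    (cycle-locked FFT amplitude spectra, surrounding-bin noise estimates,
    Z-scores, baseline-corrected amplitudes, SNR, harmonic summation),
    time-domain oddball component analysis after FFT notch filtering of the
    base rate (C1-C3), normalization of neural responses by a physical
    dissimilarity index computed from the stimulus morphs, individual
    intensity thresholds, and mixed-model group statistics with orthogonal
    polynomial trend contrasts. A synthetic-data generator produces
    recordings, morph image sets and explicit emotion-recognition trial
    tables with known ground truth so that every stage of the pipeline can
    be validated without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
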