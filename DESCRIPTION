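Package: phrenoscope
Title: Quantification of Phrenic and Diaphragm Motor Output from
    Electrophysiological and Plethysmographic Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Signal-analysis and statistics pipeline for studies of
    respiratory motor output, such as chemogenetic (DREADD) stimulation of
    phrenic motoneurons. Provides zero-phase Butterworth filtering and
    rectified-integrated envelope extraction for diaphragm EMG and phrenic
    neurograms, inspiratory burst detection with per-burst peak-to-peak,
    tonic and area-under-curve quantification, barometric (whole-body)
    plethysmography with Drorbaugh-Fenn tidal volume, arterial-pressure
    beat analysis (systolic, diastolic, mean arterial pressure, heart
    rate), epoch-based baseline normalization with death censoring and
    preparation quality-control rules, histology quadrant tallies, and the
    associated statistical battery (repeated-measures ANOVA with Tukey
    post hoc and Greenhouse-Geisser correction, paired t, Yates-corrected
    chi-squared, Pearson correlation, and a normality gate dispatching
    nonparametric equivalents). A synthetic-data module generates EMG,
    neurogram, arterial-pressure and plethysmograph traces with exact
    ground truth so every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'signal.R'
    'detect.R'
    'io.R'
    'metrics.R'
    'phrenoscope-package.R'
    'pipeline.R'
    'stats.R'
    'run.R'
    'simulate.R'
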