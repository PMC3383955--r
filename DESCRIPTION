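Package: fittsERP
Title: Simulation and ERP Analysis of a Pre-Cued Fitts Tapping Experiment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying Fitts's law during movement preparation with
    EEG. Provides a synthetic-data generator for a pre-cued bimanual tapping
    experiment (factorial target width by index-of-difficulty design with
    directional and no-go cues), EDF/TSV/JSON input and output, an ERP
    preprocessing chain (regression-based ocular correction, zero-phase
    Butterworth band-pass filtering, epoching, baseline correction,
    peak-to-peak artifact rejection, condition averaging), behavioural
    reduction (reaction/movement-time extraction, outlier trimming, error
    tabulation, Fitts regressions), and derived ERP measures (posterior
    N2/P3b region-of-interest means, motor contingent negative variation,
    lateralized readiness potential, lateralized horizontal EOG), together
    with an end-to-end pipeline that reports every regression and test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'stats.R'
    'behaviour.R'
    'config.R'
    'design.R'
    'epochs.R'
    'erp-measures.R'
    'filter.R'
    'fittsERP-package.R'
    'io-edf.R'
    'io-tables.R'
    'ocular.R'
    'simulate-behaviour.R'
    'simulate-recording.R'
    'pipeline.R'
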