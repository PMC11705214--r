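Package: diademux
Title: Demultiplexing of Top-Down DIA Mass Spectrometry Feature Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts deconvoluted top-down data-independent acquisition
    (DIA) LC-MS/MS feature data into pseudo non-multiplexed MS/MS spectra.
    Single-charge proteoform features (SCPFs) are matched to co-eluting
    fragment features in the same isolation window through a three-round
    filtering cascade: an apex cycle distance gate, a logistic-regression
    score over three chromatographic attributes, and an Averagine-based
    fragment budget split by mass. Includes spectrum-level noise estimation
    and signal-to-noise peak filtering, a training harness for the scoring
    model with b/y-ion labeling, duplicate-proteoform removal and multi-run
    merging, and a synthetic DIA-run generator with ground-truth provenance
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, pROC
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
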