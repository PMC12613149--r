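Package: timscreen
Title: Suspect Screening with Trapped Ion Mobility LC-HRMS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotation and interference classification in
    liquid chromatography - trapped ion mobility - high resolution mass
    spectrometry (LC-TIMS-HRMS) screening. Provides single-field collision
    cross section (CCS) calibration in the Mason-Schamp form, extraction of
    ion chromatograms and mobilograms from 4D centroided peak clouds, peak
    detection, m/z - retention time - CCS annotation windows with
    classification of matrix interferences and false-positive annotations,
    mobility-gated MS2 spectral extraction with cosine library matching and
    identification-confidence levels, desk-scale evaluation experiments
    (retention-time window widening, spectral coverage, charge-state
    trendline fits, cross-sample feature alignment), and a synthetic 4D
    data generator with a ground-truth ledger for benchmarking the whole
    workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
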