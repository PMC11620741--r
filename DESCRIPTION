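Package: mcellmsi
Title: Multisensory Integration Analysis for Mauthner-Cell Intracellular Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Windowed quantification of Mauthner-cell membrane-potential traces and the
    derived multisensory-integration statistics: phasic/tonic decomposition of tectal
    train responses, MSI/Max and MSI/Sum indices, S1-S2 sequence-integration indices,
    feed-forward shunting-inhibition (%SI) time courses with peak, half-decay and
    area-under-curve metrics, and inverse-effectiveness regression. Includes a
    single-compartment conductance-based Mauthner-cell simulator with modality-specific
    excitatory kernels and shunting feed-forward inhibition, a plain-text trial bundle
    format, a minimal Axon Binary Format (ABF1) importer, and end-to-end pipeline
    drivers reproducing the study's figure-level summary tables on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
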