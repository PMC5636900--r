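Package: ptarget
Title: Predicting Subcortical Targets of Cortical Pyramidal Tract Neurons
    from Structure and In Vivo Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the structure of cortical pyramidal
    tract (PT) neurons (soma depth, laminar dendrite distributions from SWC
    reconstructions) and their in vivo function (ongoing and whisker-evoked
    spiking) to their subcortical axonal targets. Implements peristimulus
    time histogram (PSTH) metrics and similarity indices, laminar dendritic
    morphometry, retrograde soma-density profiling, and a Mahalanobis
    distance classifier with chi-squared assignment confidences. A
    synthetic-cohort generator calibrated to published group statistics
    drives every stage, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
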