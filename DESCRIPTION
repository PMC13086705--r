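Package: neckconn
Title: Axon Morphometry and Conduction Velocity Analysis for Insect Neck
    Connectives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of insect neck connectives from
    transmission electron microscopy and multi-shank extracellular
    recordings. Provides TEM tile preprocessing (dark-pixel clipping,
    flat-field correction, contrast-limited adaptive histogram
    equalization), axon morphometry from label masks (connected-component
    labeling, equivalent-circle diameters, spatial distributions),
    ensheathing-glia scaling fits from membrane traces, conduction-velocity
    estimation by pairwise waveform cross-correlation with sub-sample lag
    refinement and multiplexed-ADC timing correction, and kernel-density
    maximum-likelihood estimation of the velocity-diameter scaling exponent
    with BCa bootstrap intervals. A synthetic-data module generates axon
    populations, sheath datasets, probe recordings, and tile stacks with
    known ground truth so every stage is testable without microscopy or
    electrophysiology data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
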