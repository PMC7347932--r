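Package: nanoxrf
Title: Quasi-Correlative Nano-XRF Quantification of Subcellular Trace Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for synchrotron X-ray fluorescence (XRF)
    nano-imaging of thin tissue sections combined with transmission electron
    microscopy (TEM) ultrastructure. Registers compartment and organelle masks
    drawn on TEM mosaics onto XRF count maps with a fiducial-based similarity
    transform, sums spectra over masks and deconvolutes elemental K-lines,
    computes per-compartment relative count-rate contrasts with Poisson
    uncertainty propagation, calibrates counts to areal masses and ppm
    concentrations against a thin-film multilayer standard with internal Si
    normalization, and detects sub-micron Fe/S-rich cytoplasmic granules by
    k-sigma thresholding. Includes a synthetic neuron-phantom generator so the
    whole pipeline is testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    knitr,
    rmarkdown,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
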