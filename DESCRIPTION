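Package: prcpet
Title: Positron Range Corrected PET Reconstruction with Tissue-Dependent
    Annihilation Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for small-animal
    rubidium-82 PET with positron range correction (PRC). Models the
    annihilation point-spread function of the Rb-82 positron, scales it to
    arbitrary tissue densities through the water-equivalent distance, and
    discretizes it into convolution kernels that are either uniform per
    segmented tissue class (tissue-dependent, TD) or spatially variant
    through ray-averaged densities across tissue boundaries (TDSV). The
    kernels are embedded in an ordered-subset expectation-maximization
    (OSEM) reconstruction with a matched projector pair. Includes digital
    phantoms (NEMA NU-4 style image-quality phantom, a two-compartment
    cardiac phantom, a breathing rat-thorax phantom with optional infarct),
    a Poisson acquisition simulator with attenuation and detector blur,
    respiratory gating, and the NEMA NU-4 / line-profile metric suite
    (percent standard deviation, spillover ratio, recovery coefficients,
    FWHM/FWTM, Butterworth post-filter).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    yaml,
    minpack.lm
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
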