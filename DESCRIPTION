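Package: dlept
Title: Deep-Learning and Helmholtz Electrical Properties Tomography from
    Simulated MR Transmit Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolbox for magnetic resonance
    electrical properties tomography (MR-EPT) at 3 Tesla (128 MHz). Generates
    two-dimensional tissue models (homogeneous cylindrical phantoms, head-like
    white matter/gray matter/CSF label maps, tumor inclusions) with literature
    dielectric properties, computes complex transmit (B1+) and receive (B1-)
    radiofrequency field maps with a frequency-domain electromagnetic solver
    under quadrature birdcage-like excitation, and injects calibrated thermal
    noise. Conductivity and relative permittivity maps are reconstructed both
    analytically via the Helmholtz equation (noise-robust Savitzky-Golay
    Laplacian kernels) and with a conditional generative adversarial network
    (U-Net generator, PatchGAN discriminator) trained on the simulated fields.
    Includes per-tissue evaluation statistics, noise-level sweeps, and a tumor
    detection experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
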