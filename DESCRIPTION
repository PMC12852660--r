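Package: sminr
Title: Self-Supervised Implicit Neural Representation Fitting of the Standard
    Model of White Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of Standard Model (SM) white-matter kernel
    parameters (intra-axonal fraction and diffusivity, extra-axonal axial and
    perpendicular diffusivity, non-weighted signal) and the fiber orientation
    distribution (even-order real spherical harmonics up to order eight) from
    b-tensor-encoded diffusion MRI. A coordinate network with Fourier-feature
    spatial encoding is trained directly against the measured signal through
    the stick-plus-zeppelin forward model (analytic Funk-Hecke convolution or
    spherical Simpson quadrature), with mean-squared-error or Rician
    log-likelihood losses, a fiber-orientation-distribution non-negativity
    penalty, and optional per-voxel effective acquisition protocols for
    gradient non-uniformity correction. Includes a synthetic phantom
    generator, a multi-start voxel-wise nonlinear least-squares baseline,
    continuous spatial upsampling, and evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
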