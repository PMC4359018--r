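Package: qsmsim
Title: Simulating Susceptibility and Microstructure Effects in Gradient-Echo MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward simulation and inversion of magnetic-susceptibility
    effects in gradient-echo MRI. Implements Fourier dipole-kernel field
    models for scalar, cylindrically symmetric, and full tensor
    susceptibility distributions; SHARP spherical-mean-value background
    field removal; multi-orientation external-field susceptometry of an
    embedded white-matter sample with a sin-squared orientation model for
    microstructure-related residual frequency offsets; synthetic
    nerve-in-sphere phantom and digital brain model generators; thresholded
    k-space division (TKD) quantitative susceptibility mapping; and
    conjugate-gradient susceptibility tensor imaging (STI) with
    eigen-analysis into isotropic/anisotropic maps and principal
    eigenvector fiber estimates. Evaluation utilities quantify the
    artifacts that white-matter microstructure frequency offsets introduce
    into QSM and STI reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
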