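Package: micromig
Title: Cell Migration Statistics and Microstructure Morphometrics for
    Bicontinuous Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of 3D cell migration and two-phase hydrogel
    microstructure. Implements the anisotropic persistent random walk (APRW)
    inference chain for cell trajectories (time-averaged mean squared
    displacement, angular displacement distributions, singular-value
    decomposition of the velocity matrix into primary and non-primary
    migration axes, joint nonlinear least-squares fitting of the per-axis MSD
    model, diffusivities and anisotropy index) together with a seeded APRW
    trajectory simulator; morphometrics of labeled two-phase volumes (volume
    fraction, largest-component connectivity, interfacial surface area per
    volume, object counts, intensity coefficient of variation); spheroid
    outgrowth, oriented-bounding-box perpendicular extent and tissue
    infiltration statistics; and Hertz spherical-indentation modulus fitting
    with force-map interquartile-range outlier statistics. All inputs the
    analyses consume can be generated synthetically from seeded
    configurations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
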