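Package: vctbench
Title: Reproducible Virtual-CT Benchmarking: Phantoms, Simulation,
    Reconstruction and Audited Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for constructing reproducible virtual computed-tomography
    (vCT) benchmarks. Provides digital phantom construction from ellipse and
    ellipsoid vector models or material weight masks, Hounsfield-unit and
    linear-attenuation-coefficient conversion against a tabulated
    energy-dependent material dictionary, analytic and voxel-driven
    parallel-beam projection with polychromatic spectra and Poisson photon
    noise, sinogram degradation (sparse, limited-angle, random subsampling,
    low dose), water (beam-hardening) correction, filtered back projection,
    analytical ground-truth synthesis, masked full-reference and regional image
    quality assessment, and dataset packaging with a machine-readable
    reproducibility-checklist manifest and an independent package auditor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
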