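Package: fwlesion
Title: Free-Water Imaging and Fiber-Density Analysis of White-Matter Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying extracellular free water and apparent fiber
    density in white-matter hyperintensities from single-shell diffusion MRI.
    Implements conventional diffusion-tensor fitting, per-voxel bi-tensor
    free-water elimination, single-shell 3-tissue constrained spherical
    deconvolution with apparent-fiber-density maps, lesion-mask algebra
    (normal-appearing white matter, free-water quartile subregions, lesion
    probability maps), and the accompanying cohort statistics (paired tests,
    one-way MANOVA with generalized eta squared, partial correlations,
    change-in-estimate logistic regression, Cohen's kappa). A synthetic
    diffusion-MRI phantom with known ground truth makes the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    pracma,
    withr,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
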