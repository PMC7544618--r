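Package: prfmapr
Title: Wide-Field Population Receptive Field Mapping and Visuotopic
    Cluster Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for wide-field retinotopic mapping with population
    receptive field (pRF) models. Generates rotating-wedge and
    expanding/contracting-ring aperture movies and block-design
    localizer schedules, simulates periodic BOLD responses of isotropic
    Gaussian pRFs on a synthetic cortical sheet (including "cloverleaf"
    visuotopic clusters with a shared foveal confluence), extracts and
    denoises node time courses (PCA nuisance regressors, surface-normal
    sampling, percent signal change), applies harmonic frequency-domain
    filtering, fits isotropic Gaussian pRFs by exhaustive grid search
    with Pearson-correlation selection, delineates visuotopic borders
    from polar-angle gradient reversals, and computes visual-field
    coverage statistics from summed Gaussian pRFs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
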