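Package: spheromorph
Title: Spheroid Morphometry from 2D Projections and Light-Sheet 3D Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative morphometry of multicellular spheroids (including
    multicellular aggregates of lymphoma cells grown in ultra-low attachment
    plates) from bright-field 2D projections and light-sheet (SPIM) 3D image
    stacks. Provides grayscale multi-page TIFF input/output, maximum-intensity
    projection, 2D shape descriptors (area, circularity, sphericity index,
    roundness, solidity, sphere-equivalent projected volume), a 3D
    segmentation pipeline (isotropic resampling, noise-adaptive non-local
    means denoising, Otsu-initialized hysteresis thresholding, connected
    component and cavity cleanup), 3D shape descriptors (real volume,
    mesh surface area, equivalent-ellipsoid axes, eccentricities, sphericity,
    roundness, maximum thickness and top-view diameter), propidium-iodide
    based cell-death and viability quantification, a seeded phantom generator
    with analytic ground truth, and batch orchestration with a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp (>= 1.0.0),
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
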