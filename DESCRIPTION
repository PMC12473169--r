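Package: radialsurf
Title: 3D Surface Reconstruction of Raised Skin Lesions from Radial Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a closed-form 3D model of an irregular raised
    biological surface (such as a cutaneous hemangioma) from 2D radial
    cross-section profiles acquired by rotating the object at fixed angles.
    A two-layer polynomial least-squares fit yields a bivariate coefficient
    matrix evaluable at arbitrary coordinates; the reconstructed surface is
    triangulated to compute area, elasticity-corrected skin area, volume,
    mass, mean density, centroid, and two-point resection measurements.
    Also provides silhouette-image profile extraction, a synthetic phantom
    generator for validation, a surgical-navigation error budget,
    Mahalanobis discriminant screening of resection parameters, and
    regression-based model-adequacy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
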