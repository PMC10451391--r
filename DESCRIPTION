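Package: corneaga
Title: Modal Reconstruction of Corneal Surfaces by Evolutionary Quadric Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs anterior and posterior corneal surfaces from sparse,
    incomplete Scheimpflug elevation point clouds by fitting a ten-coefficient
    implicit quadric with an elitist real-coded multivariable genetic algorithm
    (CORNEAGA), alongside classical weighted least-squares (trust-region) and
    sequential quadratic programming baselines and a closed-form direct linear
    fit. Includes a reader/writer for the 24-ring by 256-meridian polar
    elevation CSV dialect used by Sirius-style tomographers (sentinel -1000
    marks invalid samples), canonical-ellipsoid transformation with extraction
    of clinical morpho-geometric parameters (apical curvature radii and
    asphericity), elevation mean-squared-error and failure-quadric-number
    validation, a synthetic cornea generator with noise, dropout and
    keratoconus-like cone deformation, batch method comparison, and binary STL
    mesh export via Delaunay triangulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
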