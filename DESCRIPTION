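Package: aqbd
Title: Analytical Quality by Design Workflows for Separation Method
    Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the computational side of Analytical Quality by
    Design (AQbD) method development: construction of coded experimental
    designs (orthogonal central composite, Plackett-Burman, three-level
    screening arrays), Free-Wilson screening models with graphic analysis
    of effects, quadratic response-surface models with PRESS/Q2-based
    backward refinement, Monte Carlo propagation of model uncertainty to
    joint pass-probability maps and Method Operable Design Region (MODR)
    extraction, and robustness/system-suitability derivation.  Ships the
    complete development study of a cyclodextrin-modified micellar
    electrokinetic chromatography method for trimecaine impurity
    profiling as a worked fixture, together with a synthetic study
    generator for validating the whole pipeline against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
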