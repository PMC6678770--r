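Package: qsrrorder
Title: Order-Constrained QSRR Modelling of Chromatographic Elution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-retention relationship (QSRR) models for
    reversed-phase liquid chromatography that trade retention-time accuracy
    against elution-order accuracy. Fits ordinary multiple linear regression
    (MLR) control models and order-constrained models in which hinge-penalized
    relaxation variables on adjacent elution-order constraints are minimized
    jointly with the squared retention-time error, solved as a convex quadratic
    program by a primal-dual interior-point method. Includes deterministic
    Kennard-Stone training/validation splitting, percentage root-mean-square
    error metrics for retention time and elution order, leverage-based
    applicability-domain diagnostics (Williams plot), paired model comparison,
    and a synthetic retention-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
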