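Package: gomptx
Title: Gompertz Tumor Growth Under Radiotherapy and Immunotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Macroscopic modelling of tumor progression under radiotherapy
    and immunotherapy. Implements the Gompertz growth law and its closed-form
    solution, immunotherapy-perturbed dynamics with constant or exponentially
    decaying drug profiles, linear-quadratic instantaneous cell kill for
    fractionated radiotherapy with a closed-form multi-fraction course, a
    regression/extinction criterion, and a radiotherapy-triggered synergy
    (abscopal) model for unirradiated metastatic sites. A phenomenological
    fitting layer estimates effective Gompertz parameters per treatment phase
    from longitudinal tumor-size data by nonlinear least squares, with
    chi-square-per-degree-of-freedom parameter uncertainties, correlation and
    RMS relative-error goodness statistics, and day-by-day specific growth
    rate estimation. A synthetic-data module generates multi-arm study
    designs with measurement noise, and a command-line interface ties the
    pieces into simulate/fit/rate/abscopal workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
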