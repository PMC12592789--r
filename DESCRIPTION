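Package: sunjoint
Title: Semi-Parametric Joint Models for Longitudinal Data with Irregular,
    Outcome-Dependent Visit Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits semi-parametric joint models for longitudinal outcomes
    observed at irregular visit times that may depend on the outcome process
    through a shared subject-level frailty. Implements the multiplicative
    (Sun-type) outcome model with a proportional visit-intensity process:
    Andersen-Gill estimation of the visit model, Breslow estimation of the
    cumulative baseline intensity, method-of-moments frailty estimates, the
    original weighted estimating equation for relative covariate effects, and
    an extended estimating equation that additionally recovers the intercept
    function via a B-spline log-linear parameterization, giving absolute mean
    outcome trajectories. Includes a working-independence log-link marginal
    regression comparator, residual diagnostics for the intercept's
    functional form, nonparametric subject-level bootstrap inference, and a
    simulation engine for frailty-coupled visit and outcome processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
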