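Package: odeident
Title: Structural and Practical Identifiability Analysis for ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether the parameters of nonlinear
    ordinary-differential-equation models can be recovered from
    input-output data. Local structural identifiability and
    observability are tested with an exact rank condition on the
    Jacobian of stacked output Lie derivatives; small models can
    additionally be screened for output-equivalent parameter sets by
    Taylor-coefficient matching. Practical identifiability is
    quantified with forward-sensitivity equations, the Fisher
    information matrix, multistart weighted least squares, and profile
    likelihood. D-optimal experiment design optimizes constant or
    piecewise-linear input signals to maximize the determinant of the
    Fisher information matrix. A zoo of worked fermentation and
    compartmental models (digesta passage, beta-casein hydrolysis,
    rumen methanogenesis, Monod-Haldane chemostat growth) is included
    as executable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    compiler,
    deSolve,
    generics,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
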