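Package: phase23opt
Title: Utility-Based Optimization of Phase II/III Drug Development
    Programs with Discounted Phase II Estimates
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Plans two-stage (phase II to phase III) drug development
    programs with a time-to-event endpoint.  The phase II hazard-ratio
    estimate drives both the go/no-go decision and the phase III event
    number, and may first be discounted multiplicatively (retention
    factor) or additively (lower confidence bound) to counter the
    selection-induced overestimation that follows a go decision.  Under a
    Gaussian-mixture prior on the true log hazard ratio, the package
    computes expected program characteristics (probability to go,
    expected phase III events, probability of a successful program,
    benefit-category probabilities) by exact conjugate-normal reduction
    plus one-dimensional Gauss-Legendre quadrature, assembles expected
    cost, gain and utility, and finds the design (phase II events,
    decision threshold, adjustment parameter) maximizing expected
    utility over a grid, optionally under a budget constraint.  A Monte
    Carlo program simulator provides independent validation of every
    expectation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
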