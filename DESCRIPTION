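Package: qconcept
Title: Quantum Interference Models for Concept Combination Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-concept disjunction membership data with
    complex Hilbert-space interference models from quantum cognition.
    Fits a finite-dimensional interference model to per-item membership
    collapse probabilities for two concepts and their disjunction, estimating
    per-item interference budgets, phases and signs via a greedy partial-sum
    scheme. Includes classicality diagnostics (overextension and
    underextension), conversion of 7-point Likert ratings to collapse
    probabilities, a two-dimensional interfering-prototype wave-field
    renderer based on Gaussian wave packets and a polynomial phase field, the
    conjunction/negation compatibility statistic with classical and
    quantum-informed predictions, and seeded synthetic-data generators for
    every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
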