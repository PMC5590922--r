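Package: gsbup
Title: Generalized Slacks-Based Efficiency Analysis with Undesirable
    Factors, Malmquist Productivity, and a Tobit Second Stage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase efficiency analysis for panels of decision-making
    units such as hospitals. Phase I scores each unit with a generalized,
    non-oriented slacks-based data envelopment analysis model (GSBUP) that
    handles desirable and undesirable inputs and outputs under user-set
    preference weights, classifies returns to scale, projects inefficient
    units onto the best-practice frontier, and tracks productivity over
    time with a Malmquist index decomposed into technical-efficiency
    change and frontier shift. Phase II relates the efficiency scores to
    exogenous covariates through a censored-normal (Tobit) maximum
    likelihood regression. Includes seeded synthetic-data generators with
    known frontiers for end-to-end validation, and a bundled benchmark of
    the seven Hong Kong Hospital Authority clusters (2013).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
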