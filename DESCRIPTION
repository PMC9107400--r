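Package: sptkinetics
Title: Single-Molecule Tracking Kinetics for Chromatin-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-particle tracking of
    chromatin-interacting transcription factors imaged by HaloTag
    single-molecule microscopy. Links localizations into tracks, restricts
    them to nucleus masks, fits pooled jump-length distributions to a
    two-state (bound/free) diffusion kinetics model with bootstrap
    confidence intervals, segments individual tracks into bound and free
    states with a two-state gamma-emission hidden Markov model, and
    performs residence-time survival analysis with photobleaching
    correction and multi-exponential fitting. Includes a synthetic-data
    generator for switching Brownian motion with localization error and
    photobleaching, and gene-set overlap statistics (representation factor,
    directional concordance) for comparing differential-expression tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
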