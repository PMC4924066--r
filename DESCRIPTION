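Package: zinbre
Title: Zero-Inflated Negative Binomial Panel Models with Site-Specific
    Random Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum marginal likelihood estimation of hourly crash-frequency
    models on unbalanced road-segment panels: Poisson, negative binomial,
    zero-inflated Poisson and zero-inflated negative binomial models, the
    latter optionally with independent normal site-specific random effects in
    the count and zero states integrated out by Gauss-Hermite quadrature.
    Includes the Vuong non-nested test for zero inflation, an overdispersion
    decision, elasticity and pseudo-elasticity post-processing of expected
    counts, a calibrated synthetic generator of unbalanced hourly
    segment-panel data with dominant zeros, panel CSV input/output, and a
    small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr
Config/testthat/edition: 3
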