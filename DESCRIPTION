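Package: brantmix
Title: Finite-Mixture Multievent Mark-Recapture Models and Harvest
    Compensation for Long-Lived Geese
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits multievent (hidden Markov) capture-mark-recapture models
    with two-class finite-mixture ("frailty") heterogeneity in juvenile
    survival, recruitment and detection, as developed for long-term studies
    of black brant geese marked as goslings and adults at a breeding colony.
    Provides maximum-likelihood estimation with multiple random starts and
    QAIC model ranking, U-CARE-style directional goodness-of-fit components
    (transience and trap-dependence) with overdispersion estimation, a
    synthetic encounter-history generator for simulation studies, and a
    six-state two-quality matrix projection model with quality inheritance
    used to compute reproductive values, a harvest-compensation index and
    growth-rate responses to class-structured harvest scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
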