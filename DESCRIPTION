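Package: migrenv
Title: Long-Term Environmental Exposures and Migraine in EHR Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control and case-case analyses of long-term
    environmental exposures and migraine headache in electronic health record
    (EHR) cohorts. Provides inverse-distance-weighted (IDW) point-source
    exposure assessment with great-circle distances, an EHR-based migraine
    probability score with configurable component weights, frequency matching
    of controls to cases, random-intercept logistic and negative binomial
    mixed models fitted by adaptive Gauss-Hermite quadrature, penalized-spline
    exposure-response checks, Moran's I residual diagnostics with a
    permutation null, and a synthetic cohort generator with known ground
    truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
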