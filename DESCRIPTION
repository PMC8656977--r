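Package: hospeff
Title: Two-Stage Hospital Efficiency Analysis with DEA, Malmquist Productivity and Censored Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Input-oriented data envelopment analysis (DEA) of hospital panels under
    constant and variable returns to scale, with scale-efficiency decomposition,
    returns-to-scale classification and peer benchmarking; the adjacent-period
    Malmquist total-factor-productivity index with its full decomposition into
    efficiency change, technological change, pure efficiency change and scale
    efficiency change; and a second-stage left-censored (Tobit) regression of
    transformed inefficiency scores on environmental factors, with variance
    inflation factor screening and Wald-based model comparison. Includes a
    synthetic panel generator with exact Farrell ground truth for end-to-end
    validation, and packaged reference score tables for a 39-hospital national panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    statmod
Suggests:
    testthat (>= 3.0.0),
    survival,
    car,
    optparse,
    jsonlite
Config/testthat/edition: 3
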