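Package: hgsocsim
Title: Stochastic Natural-History Simulation of High-Grade Serous Ovarian
    Cancer and Ultrasound Screening Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the pre-clinical natural history of high-grade serous
    ovarian cancer (HGSOC) as piecewise Gompertzian growth punctuated by rare
    stochastic downward jumps in the growth-saturation rate, each jump raising
    the tumor's carrying capacity. Provides closed-form propagation and
    threshold-crossing kinetics, Monte Carlo cohort simulation of detection
    and life-threatening volume crossing times, the screening "window of
    opportunity" between the two, transvaginal-ultrasound (TVU) monitoring
    protocol evaluation (occult / detected / succumbed classification across
    monitoring frequencies and detection sensitivities), and estimation of
    lower-bound initial growth rates from bi-dimensional adnexal tumor
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
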