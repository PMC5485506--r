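Package: prostasim
Title: Microsimulation of Benefits and Harms of Prostate Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-time (annual-cycle) state-transition microsimulation of
    prostate cancer natural history, PSA screening, stage-specific treatment,
    active surveillance, and quality-adjusted survival. Latent disease onset and
    progression follow mixture-cure Weibull exit-time distributions; a familial
    risk factor scales onset and progression hazards. The package simulates
    paired cohorts under common random numbers to contrast screening strategies
    against no screening on lifetime risks of diagnosis, overdiagnosis,
    curative overtreatment, treatment-related adverse events, prostate cancer
    death, life days and quality-adjusted life days, and provides sensitivity
    sweeps over cure rates and disutility preferences as well as calibration of
    the familial risk factor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
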