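Package: coffeevoc
Title: Emission Kinetics and Two-Zone Exposure Modelling for Coffee Volatiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates specific emission rates (SERs) of diacetyl and
    2,3-pentanedione from small-chamber emission trials by fitting a
    first-order decaying-source concentration model with a steady-state
    asymptote, derives peak and buildup-corrected emission factors, and
    propagates the fitted rates through a probabilistic two-zone
    (near-field/far-field) mass-balance model to predict task-level and
    full-shift occupational exposures. Includes replicate and particle-size
    summaries (geometric mean/GSD, Feret diameter), storage-age trend
    regression, cyclic work-shift scenario simulation with REL/STEL
    exceedance reporting, seeded Monte Carlo uncertainty propagation, an
    inter-zone airflow sensitivity sweep, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
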