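Package: camoccu
Title: Occupancy and Conditional Co-Occurrence Models for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for single-season site-occupancy analysis of camera-trap
    data with imperfect detection: independence filtering of photographic
    records, weekly detection-history construction with ragged effort,
    covariate standardization and collinearity screening, PCA summaries of
    landscape metrics, maximum-likelihood and MCMC fitting of occupancy
    models with logit-linked covariates, two-species conditional
    co-occurrence models in the psiBa parameterization with species- and
    detection-interaction factors, model selection by AICc and PSIS-LOO
    elpd with a p-first sequential strategy, MacKenzie-Bailey
    goodness-of-fit checks (parametric bootstrap and posterior predictive),
    spatial residual diagnostics (Moran's I and distance-binned
    correlograms), and a seeded synthetic-data generator emulating a
    multi-reserve cloud-forest camera grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
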