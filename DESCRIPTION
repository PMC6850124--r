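Package: rpmsim
Title: Discrete-Event Cost-Effectiveness Microsimulation of Remote
    Patient Monitoring in ICD Recipients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-patient discrete-event simulation of
    rehospitalization and death in Medicare-aged implantable
    cardioverter-defibrillator (ICD) recipients, comparing remote patient
    monitoring (RPM) with conventional follow-up. Patients are sampled
    from published PREDICT RM categorical covariate distributions, cloned
    into both treatment arms with common random numbers, and followed
    through Weibull accelerated-failure-time equations for first
    rehospitalization and death (with a time-varying effect of the first
    rehospitalization on mortality applied by conditional event-time
    resampling), a constant-rate process for subsequent
    rehospitalizations, and deterministic outpatient claim accrual.
    Discounted life-years, quality-adjusted life-years and costs are
    aggregated into incremental cost-effectiveness results, with a
    declarative scenario engine and one-way sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
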