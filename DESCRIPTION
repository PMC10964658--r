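Package: tavicea
Title: Cost-Utility Modelling of Transcatheter Versus Surgical Aortic Valve
    Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage health-economic model comparing transcatheter aortic
    valve implantation (TAVI) with surgical aortic valve replacement (SAVR) in
    patients with severe aortic stenosis at low surgical risk. A 30-day
    decision tree for acute procedural events feeds a four-state Markov cohort
    model (alive and well, treated atrial fibrillation, disabling stroke,
    dead) run in monthly cycles over a lifetime horizon. The package computes
    discounted costs by category, quality-adjusted life years, incremental
    cost-effectiveness ratios and net benefit statistics, and provides
    deterministic (tornado) and probabilistic sensitivity analyses,
    cost-effectiveness acceptability curves, a scenario catalogue, and a
    calibration routine that solves unpublished transition and utility
    parameters against published model outputs.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
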