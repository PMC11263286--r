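Package: fittsnirs
Title: Simulation and Mixed-Model Analysis of Fitts-Law Reaching with fNIRS Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the speed-accuracy trade-off in aimed reaching
    together with motor-cortical hemodynamics measured by functional
    near-infrared spectroscopy (fNIRS). Simulates block-design reaching
    experiments (Fitts-law trial generation, 60 Hz cursor trajectories,
    44-channel oxy-hemoglobin series with hemodynamic responses, drift,
    physiological oscillations and motion artifacts), computes kinematic
    measures (index-of-difficulty, movement time, throughput, overshoot),
    implements an oxy-Hb preprocessing chain (linear detrending, temporal
    derivative distribution repair, zero-phase Butterworth band-pass),
    estimates channel-wise activation betas with a canonical double-gamma
    HRF general linear model, aggregates them into probability-weighted
    region-of-interest activations, and fits random-intercept linear and
    logistic mixed-effects models (profiled REML with Satterthwaite degrees
    of freedom; Laplace-approximated maximum likelihood) with conditional
    R-squared reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    emmeans
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
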