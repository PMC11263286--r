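# fittsnirs

Simulation and mixed-model analysis of Fitts-law reaching experiments with
synchronized motor-cortical fNIRS recordings.

## The problem

In aimed reaching, movement time grows with Fitts' index of difficulty,
`ID = log2(2D/W)` bits, for target distance `D` and width `W` — the
speed–accuracy trade-off. Whether activity in the motor cortices (primary
motor cortex BA4, premotor/supplementary motor cortex BA6, measured as
oxy-hemoglobin changes by functional near-infrared spectroscopy) is tuned
to the same scalar difficulty, or separately to distance and width, is the
scientific question this analysis chain addresses. The package is aimed at
motor-control and neurorehabilitation researchers who want a fully tested,
reproducible implementation of that analysis — and, because no public
recordings exist for the design, a synthetic-data generator that emulates
the whole experiment (16 subjects × 12 blocks × 15 trials; 2 × 2 conditions
D ∈ {200, 600} px × W ∈ {40, 120} px giving difficulty levels 1.74 / 3.32 /
4.91 bits; 60 Hz cursor trajectories; 10 Hz 44-channel oxy-Hb series with
HRF responses, drift, physiological oscillations and motion artifacts) so
every stage is validated end to end by parameter recovery.

The chain implements:

* **Kinematics** — trial classification (success / failure / overshoot from
  a 2-s entry deadline and 0.5-s hold), movement time, throughput
  `TP = mean(ID_i / MT_i)` over successful trials, overshoot rates.
* **Oxy-Hb preprocessing** — linear detrend → temporal derivative
  distribution repair (robust derivative-outlier correction) → zero-phase
  0.01–0.08 Hz third-order Butterworth band-pass, with CV > 30% channel
  exclusion and 5-s-baseline block activations.
* **Activation** — canonical double-gamma HRF GLM betas per channel ×
  condition; probability-weighted top-3-channel ROI aggregation
  `sum(P_i b_i) / sum(P_i)` over the probabilistic anatomical registration.
* **Inference** — random-intercept linear mixed models (profiled REML,
  Satterthwaite df) and logistic mixed models (Laplace / adaptive
  Gauss–Hermite), written from first principles and oracle-checked against
  lme4/lmerTest in the tests; conditional R²; Bonferroni-corrected channel
  t-tests; signed-rank ROI activation tests; pairwise condition contrasts.

## Worked example

```r
library(fittsnirs)

index_of_difficulty(c(200, 600, 200, 600), c(120, 120, 40, 40))
#> [1] 1.736966 3.321928 3.321928 4.906891

cfg <- sim_config(master_seed = 20240101)     # the full 16-subject study
trials <- simulate_behavior(cfg)
fit <- fit_lmm(MT ~ ID + (1 | subject), trials[trials$success, ])
fit$coefficients
#>          term   estimate          se         df  statistic         p
#> 1 (Intercept) 0.04114685 0.026385508   18.61271   1.559449 0.1357317
#> 2          ID 0.29792377 0.002623433 2629.10130 113.562577 0.0000000
conditional_r2(fit)
#> [1] 0.8422942
```

The fitted slope (0.298 s/bit) recovers the generating Fitts slope
0.2974 s/bit — the pooled value of the emulated study — and the intercept,
subject variance and residual variance match the generator's settings.

The numbered scripts under `analysis/` run the complete study —
`01_simulate.R` (writes trial tables, events, series and the registration
under `results/data/`), `02_kinematics.R`, `03_hemodynamics.R`,
`04_mixed_models.R`, `05_recovery.R` — each printing a short narrative.
From a run at the default seed:

```
MT ~ ID: slope 0.2979 s/bit (SE 0.0026, p 0), conditional R2 0.842
success ~ ID: -1.3143 per bit (p 3e-47), conditional R2 0.416
ROI signed-rank statistics: contra_BA4 W=136, contra_BA6 W=136,
                            ipsi_BA4 W=136, ipsi_BA6 W=136
```

i.e. movement time rises ~0.3 s per bit of difficulty, the odds of success
fall by e^1.31 per bit (generator: 1.3407), and all 16 subjects activate
both motor ROIs positively, giving the maximal signed-rank statistic
16·17/2 = 136.

## Layout

```
R/                 package code (generator, kinematics, preprocessing,
                   activation, mixed models, pipeline, I/O)
analysis/          numbered study drivers (simulate ... recovery)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette (models, parameters, design decisions)
inst/extdata/      measured probe-registration fixture (subject 04)
```
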