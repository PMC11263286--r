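---
title: "Models and methods: simulated Fitts-law reaching with motor-cortical fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulated Fitts-law reaching with motor-cortical fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fittsnirs` implements, end to end, the analysis of a block-design reaching
experiment in which healthy adults make 2D aimed movements of graded
difficulty while oxygenated-hemoglobin (oxy-Hb) responses over the motor
cortices are recorded by functional near-infrared spectroscopy (fNIRS).
Because no public recordings exist for this design, the package also contains
a first-class synthetic-data generator that produces complete experiments
with the statistical structure the analysis assumes, so every downstream
stage is testable and the whole chain can be validated by parameter
recovery. This vignette documents the models, the generator, the tunable
parameters, and the numerical decisions.

## The study design being emulated

Sixteen subjects each perform 12 blocks of 15 reaching trials. A block uses
one of four conditions — target distance $D \in \{200, 600\}$ px crossed
with target width (disc diameter) $W \in \{40, 120\}$ px — and each
condition appears three times in a randomized order. Blocks are separated by
20-second rests. One pixel corresponds to $52\,\text{cm} / 1920\,\text{px}
= 0.027$ cm of robot workspace. A trial succeeds when the cursor enters the
target within 2 s of target appearance and then stays inside continuously
for 0.5 s; a trial that entered but exited before completing the hold is an
*overshoot*. Cursor kinematics are sampled at 60 Hz and the 44-channel
oxy-Hb montage at 10 Hz.

Task difficulty is Fitts' index of difficulty,
$$\mathrm{ID} = \log_2(2D/W)\ \text{bits},$$
which yields three levels: 1.74 (D200W120), 3.32 (D600W120 and D200W40 —
the two moderate cells coincide exactly), and 4.91 (D600W40). The original
Fitts form is used rather than the Shannon form $\log_2(D/W + 1)$ because
only the former reproduces all three printed difficulty levels.

## Kinematic model and trial generation

Movement time for successful trials follows a Fitts line with a subject
random intercept:
$$\mathrm{MT}_{ij} = \beta_0 + b_i + \beta_1 \,\mathrm{ID}_{j} +
\varepsilon_{ij}, \qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij}
\sim N(0, \sigma_\varepsilon^2).$$
Defaults: slope $\beta_1 = 0.2974$ s/bit, $\sigma_b = 0.1$ s,
$\sigma_\varepsilon = 0.15$ s (Gaussian, truncated so the entry
$\mathrm{OT} + \mathrm{MT}$ respects the 2-s deadline — a symmetric noise
model keeps the linear mixed model well specified). The intercept default
(0.06 s) and the start-zone exit time (mean 0.05 s) were fixed by a
closed-form analysis of the deadline truncation: they keep the censored
fraction of successful movement times near 2% and the analytic attenuation
of the fitted slope about $2\times10^{-4}$ s/bit, i.e. negligible against
Monte-Carlo error at study scale. The cost of that choice is that simulated
block durations span roughly 18–31 s rather than exactly the 20–31 s of the
emulated study; the printed slope, the 2-s deadline and the printed block
durations cannot all hold simultaneously at the per-trial level, and the
package prioritizes the generative kinematic model that the estimators
assume.

Success is Bernoulli on the logit scale. Two parameterisations are
available: directly on difficulty,
$\operatorname{logit} p = a + c\,\mathrm{ID} + u_i$, with defaults $a = 8$,
$c = -1.3407$ per bit, $u_i \sim N(0, 0.5^2)$; or on the factorial basis
$(1, D, W, D \times W)$, whose default coefficients are the exact solution
reproducing the difficulty model at the four design cells, so both
parameterisations agree on-study. With these defaults the success
probability is ~99.8% at the easiest level, ~97% at the moderate levels and
~81% at the hardest — performance diverging as difficulty rises. Failed
trials split into never-reached, late-entry, and overshoot modes with
configurable proportions.

Cursor trajectories are minimum-jerk paths whose timing is solved so that
the synthetic record reproduces the drawn trial exactly: the path leaves
the 10-px start zone precisely at the drawn onset time and (for successes)
crosses the target boundary precisely at $\mathrm{OT} + \mathrm{MT}$.
Overshoot trials fly through the target to a point one width past its
centre, which automatically keeps the in-target dwell below the hold
requirement at the study's geometry; a safeguard rescales the movement
duration in case a custom geometry would not. Re-classifying every
simulated trajectory with `classify_trial()` reproduces the generated
flags for 100% of trials and movement times to within one 60-Hz sample
(boundary crossings are linearly interpolated between samples, so the
discretization error is far below a sample in practice).

Classification decisions where the task description is silent:

* movement time is referenced to the start-zone exit (OT), matching the
  trial-phase decomposition OT/MT/HT; the entry-referenced time is always
  recoverable as $\mathrm{OT} + \mathrm{MT}$;
* the inside-target test uses the cursor centre point; `cursor_radius`
  widens the test to disc overlap if desired;
* the 0.5-s hold may complete after the 2-s deadline, but the *entry* must
  occur within it.

## Hemodynamic generative model

Each channel's 10-Hz series is
$$y(t) = B + \delta t + \sum_c \beta_{ch,c}\, x_c(t) + \sum_k A_k
\sin(2\pi f_k t + \phi_k) + \text{artifacts} + \epsilon(t),$$
where $x_c$ is condition $c$'s block boxcar convolved with the canonical
double-gamma hemodynamic response function (HRF) and peak-normalized; the
same code path builds the GLM design matrix, so the generator and estimator
share one definition of the regressor. $B = 1$ (device units) gives the raw
series the nonzero mean a coefficient of variation needs; $\delta = 2 \times
10^{-5}$/s is a slow drift; the oscillations default to Mayer-wave
(amplitude 0.008 at 0.1 Hz), respiratory (0.004 at 0.3 Hz) and cardiac
(0.003 at 1.2 Hz) components with channel-specific random phases; artifacts
arrive as a Poisson process (0.5/min) and are single-sample spikes
(amplitude $6\times$ the noise SD) or sustained baseline shifts
($3\times$); $\epsilon$ is white with SD 0.005. True amplitudes
$\beta_{ch,c}$ default to 0.03 on contralateral motor channels, 0.015 on
ipsilateral ones and 0.005 elsewhere, scaled per condition
(1.1, 0.8, 0.9, 1.2 for D200W120, D600W120, D200W40, D600W40) to create a
distance-by-width interaction like the one the analysis is designed to
detect. Amplitudes are in the same arbitrary concentration units as the
series; only ratios matter to the inferential results.

Every stochastic element draws from a child seed derived deterministically
from the master seed and the (subject, channel, block, trial) coordinates,
so identical configurations are bit-reproducible and any slice can be
regenerated in isolation.

The probe registration table embeds the measured channel-to-anatomy rows of
the reference subject (channels 14–16, 24–26, 32–36 with their Brodmann
labels, MNI coordinates and registration probabilities) verbatim, and fills
the remaining channels synthetically from the probe's ROI layout
(contralateral BA4 channels 14–18/23–26, contralateral BA6 32–36/41–44,
mirrored ipsilaterally). Synthetic rows are placeholders with plausible
coordinates and probabilities, not anatomical ground truth.

## Preprocessing chain

The fixed order is (1) linear detrending, (2) temporal derivative
distribution repair (TDDR), (3) zero-phase third-order Butterworth band-pass
at 0.01–0.08 Hz (`signal::filtfilt`, so the effective magnitude response is
the squared single-pass response and the phase is exactly zero — phase
distortion would shift the GLM betas). Channels whose *raw* series has a
coefficient of variation above 30% are excluded before processing (after
detrending or band-passing the mean is forced to zero and a CV is
undefined). The first and last $1/f_{low} = 100$ s are flagged as filter
edge regions in the output metadata.

**TDDR design.** The classical TDDR algorithm soft-reweights the temporal
derivative of the sub-0.5 Hz component with Tukey's biweight and
re-integrates. Two properties make that form unsuitable here, both verified
against the reference implementation: on a noiseless block-design signal
the robust scale collapses to the signal's own derivative scale, so the
hemodynamic transitions themselves are rejected as outliers (64% RMS
change); and soft-shrinking *inlier* derivatives re-integrates into a
random-walk drift that can exceed the artifact being repaired (a
single-sample spike's error grew ~11-fold). The package therefore keeps the
statistical core — Tukey-biweight IRLS (c = 4.685, MAD scale, convergence
tolerance $10^{-6}$, at most 50 iterations) for a robust location and scale
of the derivative — but applies it to residuals about a robust *local
trend* (a 1-s running median of the derivative), and repairs only residual
runs beyond the biweight rejection point, as events: a run whose net
derivative is preserved under repair is impulse-like (spike: a cancelling
pair of outliers), while a run whose outlier-sized net also appears as a
sustained median-level change across the event is a baseline shift and has
its net removed. Inliers pass through exactly. Consequences, measured on
the generator's signals: clean signals change by ~0.06% RMS (a constant
series is returned bit-identically), a 6-noise-SD spike's RMSE to the clean
reference falls ~37-fold and a baseline shift's ~270-fold, and on noisy
series the repair is never worse than no correction. Artifacts below the
rejection point relative to the noise floor are deliberately left to the
band-pass, which removes most single-sample spike energy anyway.

Block activation is the mean signal over a block's task phase (onset to
block end) minus the mean over the 5 s immediately preceding the onset;
blocks without 5 s of pre-onset data are skipped with a warning (the
session layout, with a rest before the first block, always provides it).

## Activation estimation

The channel GLM regresses the preprocessed series on one HRF-convolved
boxcar per condition plus an intercept, by ordinary least squares. The HRF
is the canonical double-gamma (gamma-density difference with shapes 6 and
16, unit dispersions, peak:undershoot 6:1, peak normalized to 1); no
derivative terms and no extra drift regressors are included, because
detrending and the 0.01-Hz high-pass precede the GLM. No prewhitening is
applied — inference happens at the subject level, not per time point. One
beta per condition is estimated (the three blocks of a condition share a
regressor). When the series carries preprocessing parameters, the condition
regressors are passed through the same detrend and band-pass as the data;
otherwise the temporal filtering attenuates conditions differentially
(blocks of different lengths have different spectra) and can even reorder
betas. With matched filtering, a noiseless session is identified exactly
(to $10^{-8}$, verified channel-wise in the tests).

Region-of-interest values weight the top-3 channels of an ROI by
registration probability:
$$\beta_{ROI} = \frac{\sum_{i=1}^{3} P_i\,\beta_i}{\sum_{i=1}^{3} P_i},$$
with channels ranked by probability (ties broken deterministically towards
the lower channel id) among those registered to the ROI's hemisphere and
Brodmann label and retained by the CV screen; if fewer than three are
available, all are used with a warning. The value is a convex combination
of the contributing betas and invariant to rescaling all probabilities.

## Mixed-effects estimation

The package's random-intercept fitters are written from first principles
against the closed-form inverse available for a single grouping factor,
$V_j = \sigma_\varepsilon^2 I + \sigma_b^2 J$.

**Linear (REML).** The REML criterion is profiled down to a bounded scalar
search over $\log\theta$, $\theta = \sigma_b^2/\sigma_\varepsilon^2$,
on $[\log 10^{-8}, \log 10^{8}]$ with tolerance $10^{-10}$
(`stats::optimize`); fixed effects are the GLS solution at the optimum,
computed from per-group sufficient statistics in $O(n)$. A boundary
solution ($\theta \to 0$) is reported as a *singular* fit, not an error,
and reduces to ordinary least squares. Degrees of freedom use the
Satterthwaite approximation: for each coefficient,
$\nu = 2 f(\hat\sigma)^2 / (g^\top A g)$ where $f$ is the coefficient's
variance as a function of the two variance components, $g$ its numeric
gradient, and $A$ the inverse observed REML information (numeric Hessian,
central differences with per-parameter relative steps). On fixtures the
estimates, standard errors, Satterthwaite df and p-values agree with the
reference implementations (`lme4`/`lmerTest`) to the tolerances asserted in
the test suite ($10^{-4}$ relative on estimates).

**Logistic (Laplace / adaptive Gauss–Hermite).** The marginal likelihood
integrates the subject intercepts out by a Laplace approximation around the
per-group posterior modes (damped Newton, all groups simultaneously);
`agq > 1` refines the integral with adaptive Gauss–Hermite quadrature whose
nodes come from the Golub–Welsch eigendecomposition. The outer optimization
is L-BFGS-B over $(\beta, \log\sigma)$ with $\log\sigma$ bounded in
$[\log 10^{-4}, \log 100]$, started deterministically from the plain
logistic fit and $\sigma = 1$; fixed-effect columns are standardized
internally and transformed back (coefficients and covariance) so
raw-pixel-scale designs remain well conditioned. Inference is Wald on the
numeric observed information. Coefficients diverging beyond $\pm 30$ on the
standardized scale abort with a complete-separation diagnostic.

**Conditional $R^2$.** For a fit with fixed-effect predictions $\hat\eta$,
$$R^2_c = \frac{\operatorname{var}(\hat\eta) + \sigma_b^2}
{\operatorname{var}(\hat\eta) + \sigma_b^2 + \sigma_{res}^2},$$
with $\sigma_{res}^2 = \pi^2/3$ on the latent scale for the logistic
family. The reference package computing this quantity is not a dependency;
the formula is cross-checked in the tests against the same decomposition
computed from an independent `lme4` fit.

**Univariate tests.** Channel-wise activations are tested against zero with
one-sample t-tests, Bonferroni-corrected within condition across the tested
channels. ROI activations use the one-sample Wilcoxon signed-rank test
(exact p for $n \le 25$): with 16 subjects all activating positively the
statistic is the maximal rank sum $16 \cdot 17/2 = 136$. The two-sample
rank-sum test is also provided; the signed-rank form is what the default
report uses for ROI-against-zero comparisons, since that is the form whose
maximal statistic an all-positive sample of 16 produces. Pairwise condition
contrasts on success probability are Wald tests of differences of
model-predicted cell means on the linear predictor (random effect at zero),
Bonferroni-adjusted over the six pairs — the adjustment method is a
package choice where the emulated analysis names only its software.

**The eight reported models.** `run_paper_models()` fits success ~ D + W +
D×W and success ~ ID (logistic), MT ~ ID and MT ~ D + W + D×W (linear, on
successful trials), and beta ~ ID and beta ~ D + W + D×W per contralateral
ROI, each with a subject random intercept, and tabulates coefficients,
standard errors, p-values and conditional $R^2$.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: analytic
(filter magnitude responses, hand-computed weighted means, closed-form
logistic probabilities), brute-force (direct convolution, windowed means,
enumeration of all $2^n$ sign patterns for the exact signed-rank p),
round-trip (trajectory re-classification), reference implementations
(`lme4`, `lmerTest`, `emmeans`), and Monte-Carlo parameter recovery. The
recovery experiments regenerate the full behavioural study (16 subjects ×
180 trials) 50 times and require the mean fitted Fitts slope and logistic
difficulty coefficient to sit within two Monte-Carlo standard errors of the
generating values; a type-I-error calibration (1000 null replicates at 16 ×
20 observations) checks the LMM slope test's size stays in [3%, 7%] at
nominal 5%. Unit-level property tests use smaller sizes (8–16 subjects,
20–120 observations per subject, 200–600 s of signal) chosen so each block
exercises the asymptotics it needs; the analysis scripts under `analysis/`
run the full 16-subject study.

## What the generator does not emulate

Synthetic data make every stage testable but show only what they contain.
The generator does not produce raw light intensities (inputs are already
oxy-Hb concentrations), deoxy-Hb channels, head-motion-coupled optode
geometry, robot handle dynamics, serially correlated physiological noise
(oscillation phases are fixed per channel, noise is white), learning or
fatigue across blocks, or between-channel noise correlations. Passing tests
therefore demonstrate that the estimation chain is correct for data with
this structure — not that real recordings satisfy the structure.
Conditional $R^2$ values, block durations, throughput and per-channel
significance patterns from real data depend on quantities the generator
fixes by assumption and are reported by the pipeline as descriptive
outputs, not asserted as reproductions.

## Known limitations

* Random slopes, crossed random effects and Kenward–Roger df are out of
  scope; the fitters support exactly one random intercept.
* The GLMM's Wald standard errors use numeric observed information; they
  can differ from expected-information standard errors in small samples.
* TDDR leaves artifacts below its rejection point untouched by design;
  spikes near the noise floor survive to the band-pass.
* The CV screen assumes the device baseline offset dominates the channel
  mean; a channel with near-zero mean is flagged as excluded.
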