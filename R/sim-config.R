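# Configuration of the synthetic reaching + fNIRS experiment generator.

#' Default 2x2 condition set of the reaching task
#'
#' Distances 200/600 px crossed with widths 40/120 px, giving three
#' difficulty levels (1.74, 3.32, 3.32, 4.91 bits).
#' @return data.frame with `condition`, `D`, `W`, `ID`.
#' @export
default_conditions <- function() {
  rbind(task_condition(200, 120), task_condition(600, 120),
        task_condition(200, 40), task_condition(600, 40))
}

#' Channel sets of the motor regions of interest
#'
#' Channel ids of the four ROIs on the 44-channel probe: contralateral
#' (left-hemisphere, right-hand task) and ipsilateral primary motor cortex
#' (BA4) and premotor/supplementary motor cortex (BA6).
#' @return named list of integer channel vectors.
#' @export
roi_channels <- function() {
  list(contra_BA4 = c(14:18, 23:26),
       contra_BA6 = c(32:36, 41:44),
       ipsi_BA4 = c(9:13, 19:22),
       ipsi_BA6 = c(27:31, 37:40))
}

# Success-probability coefficients on the (1, D, W, D*W) basis that reproduce
# logit = intercept + id_coef * log2(2D/W) exactly at the four cells of the
# standard 2x2 design, so the factorial and the difficulty parameterisations
# agree on-study.
default_success_coefs <- function(intercept = 8, id_coef = -1.3407) {
  cells <- default_conditions()
  X <- cbind(1, cells$D, cells$W, cells$D * cells$W)
  as.numeric(solve(X, intercept + id_coef * cells$ID))
}

# Condition-scaled true response amplitudes for all 44 channels. ROI channels
# respond strongly with a distance-by-width interaction pattern (largest at
# the extreme-difficulty cells), off-ROI channels weakly.
default_beta_map <- function(conditions = default_conditions(),
                             base_contra = 0.03, base_ipsi = 0.015,
                             base_other = 0.005) {
  rois <- roi_channels()
  base <- rep(base_other, 44)
  base[c(rois$contra_BA4, rois$contra_BA6)] <- base_contra
  base[c(rois$ipsi_BA4, rois$ipsi_BA6)] <- base_ipsi
  scale <- c(D200W120 = 1.1, D600W120 = 0.8, D200W40 = 0.9, D600W40 = 1.2)
  sc <- scale[conditions$condition]
  sc[is.na(sc)] <- 1                      # conditions outside the 2x2 design
  bm <- outer(base, sc)
  dimnames(bm) <- list(sprintf("ch%02d", 1:44), conditions$condition)
  bm
}

#' Configuration of the synthetic experiment generator
#'
#' Bundles every tunable of the generative model. The defaults reproduce the
#' study design: 16 subjects, 12 blocks (4 conditions x 3 repetitions in
#' random order), 15 trials per block, 20-s rests, 2-s entry deadline, 0.5-s
#' hold, 60 Hz kinematics, 10 Hz fNIRS. Movement time follows a Fitts line
#' `MT = mt_intercept + mt_slope * ID` with a Gaussian subject intercept and
#' residual noise; trial success is Bernoulli with a logistic model on either
#' the factorial `(1, D, W, D*W)` basis (`success_model = "dw"`) or directly
#' on difficulty (`success_model = "id"`).
#'
#' @param n_subjects number of subjects.
#' @param conditions data.frame of conditions (see [default_conditions()]).
#' @param reps_per_condition blocks per condition.
#' @param trials_per_block trials per block.
#' @param rest_duration inter-block (and initial) rest, seconds.
#' @param trial_timeout target-entry deadline, seconds.
#' @param hold_duration required in-target hold, seconds.
#' @param kin_rate cursor sampling rate, Hz.
#' @param nirs_rate oxy-Hb sampling rate, Hz.
#' @param mt_intercept,mt_slope Fitts line, seconds and seconds per bit.
#' @param subject_intercept_sd SD of the subject MT intercept, seconds.
#' @param mt_noise_sd residual MT noise SD, seconds (Gaussian, truncated to
#'   keep successful entries inside the deadline).
#' @param ot_mean,ot_sd start-zone exit time distribution, seconds.
#' @param success_model `"dw"` or `"id"`.
#' @param success_coefs coefficients (intercept, D, W, DW) on the logit scale;
#'   default derived so that the factorial model matches
#'   `logit = success_id_coefs[1] + success_id_coefs[2] * ID` at the design cells.
#' @param success_id_coefs (intercept, per-bit slope) on the logit scale.
#' @param success_subject_sd SD of the subject random intercept, logit units.
#' @param fail_reach_frac fraction of failed trials that still reach the target
#'   (late entries or overshoots).
#' @param overshoot_frac fraction of reaching failures that exit before the
#'   hold completes (overshoots).
#' @param traj_jitter endpoint jitter of successful reaches as a fraction of
#'   the target radius (0 puts the endpoint exactly on the target centre).
#' @param start_radius start-zone radius used for onset-time detection, px.
#' @param beta_map 44 x n-conditions matrix of true hemodynamic amplitudes.
#' @param channel_baseline raw-signal baseline offset (device units), gives
#'   the unprocessed series a nonzero mean so a coefficient of variation is
#'   well defined.
#' @param drift_slope linear drift, amplitude per second.
#' @param osc_amps_freqs list of `c(amplitude, Hz)` physiological oscillations
#'   (defaults: Mayer ~0.1 Hz, respiration ~0.3 Hz, cardiac ~1.2 Hz).
#' @param artifact_rate motion-artifact events per minute per channel.
#' @param artifact_spike_gain spike amplitude as a multiple of `noise_sd`.
#' @param artifact_shift_gain baseline-shift amplitude as a multiple of
#'   `noise_sd`.
#' @param noise_sd white measurement noise SD.
#' @param master_seed integer master seed; all child streams derive from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 16,
                       conditions = default_conditions(),
                       reps_per_condition = 3,
                       trials_per_block = 15,
                       rest_duration = 20,
                       trial_timeout = 2,
                       hold_duration = 0.5,
                       kin_rate = 60,
                       nirs_rate = 10,
                       mt_intercept = 0.06,
                       mt_slope = 0.2974,
                       subject_intercept_sd = 0.1,
                       mt_noise_sd = 0.15,
                       ot_mean = 0.05,
                       ot_sd = 0.015,
                       success_model = c("dw", "id"),
                       success_id_coefs = c(8, -1.3407),
                       success_coefs = default_success_coefs(
                         success_id_coefs[1], success_id_coefs[2]),
                       success_subject_sd = 0.5,
                       fail_reach_frac = 0.7,
                       overshoot_frac = 0.6,
                       traj_jitter = 0.25,
                       start_radius = 10,
                       beta_map = default_beta_map(conditions),
                       channel_baseline = 1,
                       drift_slope = 2e-5,
                       osc_amps_freqs = list(c(0.008, 0.1), c(0.004, 0.3),
                                             c(0.003, 1.2)),
                       artifact_rate = 0.5,
                       artifact_spike_gain = 6,
                       artifact_shift_gain = 3,
                       noise_sd = 0.005,
                       master_seed = 42) {
  success_model <- match.arg(success_model)
  cfg <- as.list(environment())
  for (f in c("rest_duration", "trial_timeout", "hold_duration",
              "kin_rate", "nirs_rate"))
    if (cfg[[f]] <= 0) stop_domain("sim_config: %s must be > 0", f)
  for (f in c("n_subjects", "reps_per_condition", "trials_per_block"))
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop_domain("sim_config: %s must be a positive integer", f)
  if (!is.data.frame(conditions) || nrow(conditions) < 1)
    stop_domain("sim_config: conditions must be a non-empty data.frame")
  if (nrow(beta_map) != 44 || ncol(beta_map) != nrow(conditions))
    stop_domain("sim_config: beta_map must be 44 x n_conditions")
  if (abs(master_seed) >= 2^31)
    stop_domain("sim_config: master_seed must be a 32-bit integer")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic reaching + fNIRS experiment configuration\n")
  cat(sprintf("  %d subjects, %d conditions x %d reps x %d trials\n",
              x$n_subjects, nrow(x$conditions), x$reps_per_condition,
              x$trials_per_block))
  cat(sprintf("  rest %gs, timeout %gs, hold %gs; %g Hz kin, %g Hz fNIRS\n",
              x$rest_duration, x$trial_timeout, x$hold_duration,
              x$kin_rate, x$nirs_rate))
  cat(sprintf("  MT = %.3f + %.4f * ID (subject SD %.2f, noise SD %.2f)\n",
              x$mt_intercept, x$mt_slope, x$subject_intercept_sd,
              x$mt_noise_sd))
  cat(sprintf("  master seed %d\n", x$master_seed))
  invisible(x)
}

#' Build a simulation configuration from a YAML file
#'
#' Reads a flat key-value YAML file whose keys mirror the [sim_config()]
#' arguments and merges it onto the defaults. Conditions may be given as a
#' list of `{D, W}` pairs; `osc_amps_freqs` as a list of `[amplitude, hz]`
#' pairs. Fields not present keep their defaults.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$conditions))
    raw$conditions <- do.call(rbind, lapply(raw$conditions, function(cw)
      task_condition(cw$D, cw$W)))
  if (!is.null(raw$osc_amps_freqs))
    raw$osc_amps_freqs <- lapply(raw$osc_amps_freqs, as.numeric)
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown))
    stop_domain("sim_config_from_yaml: unknown field(s): %s",
                paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}
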