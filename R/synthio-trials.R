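# Synthetic block schedules, trial outcomes and cursor trajectories.

# Minimum-jerk position fraction s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5,
# monotone from 0 to 1 on [0, 1].
mj_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 + tau * (-15 + 6 * tau))
}

# Inverse of mj_s by bisection-free root finding.
mj_tau <- function(s) {
  vapply(s, function(si) {
    if (si <= 0) return(0)
    if (si >= 1) return(1)
    stats::uniroot(function(x) mj_s(x) - si, c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}

# Entry/exit times of an overshooting pass: a single minimum-jerk movement of
# duration T from the start (distance D from the target centre) straight
# through the target to an endpoint r_over px beyond the centre, with the
# start-zone exit pinned at OT. Returns the implied boundary times.
overshoot_times <- function(D, W, OT, T_move, r_over, start_radius) {
  total <- D + r_over
  tau_ot <- mj_tau(start_radius / total)
  tau_in <- mj_tau((D - W / 2) / total)
  tau_out <- mj_tau((D + W / 2) / total)
  t_go <- OT - tau_ot * T_move
  list(t_go = t_go, t_entry = t_go + tau_in * T_move,
       t_exit = t_go + tau_out * T_move,
       dwell = (tau_out - tau_in) * T_move)
}

#' Generate a subject's randomized block schedule
#'
#' Permutes `reps_per_condition` copies of each condition into a random block
#' order (seeded deterministically from the master seed and the subject id),
#' simulates the subject's trials to obtain per-block durations (trials
#' advance immediately on completion, so a block lasts the sum of its trial
#' durations), and lays the blocks out with `rest_duration` seconds of rest
#' before each block.
#'
#' @param config a [sim_config()].
#' @param subject subject id (integer).
#' @return data.frame of class `block_schedule`: `subject`, `block`,
#'   `condition`, `onset` (s), `duration` (s).
#' @export
generate_schedule <- function(config, subject) {
  stopifnot(inherits(config, "sim_config"))
  n_cond <- nrow(config$conditions)
  n_blocks <- n_cond * config$reps_per_condition
  order <- with_seed(child_seed(config$master_seed, "schedule", subject),
                     sample(rep(seq_len(n_cond), config$reps_per_condition)))
  sched <- data.frame(subject = subject, block = seq_len(n_blocks),
                      condition = config$conditions$condition[order],
                      onset = NA_real_, duration = NA_real_,
                      stringsAsFactors = FALSE)
  class(sched) <- c("block_schedule", "data.frame")
  trials <- simulate_trials(sched, config, .need_onsets = FALSE)
  durs <- vapply(split(trials$duration, trials$block), sum, numeric(1))
  sched$duration <- as.numeric(durs[as.character(sched$block)])
  sched$onset <- config$rest_duration +
    cumsum(c(0, utils::head(sched$duration + config$rest_duration, -1)))
  sched
}

#' Simulate trial outcomes for a block schedule
#'
#' Draws every trial of the schedule from the generative model: movement time
#' follows the Fitts line `mt_intercept + subject_intercept + mt_slope * ID`
#' plus Gaussian noise (truncated so that successful entries respect the
#' deadline), and the success outcome is Bernoulli with a logistic model on
#' `(1, D, W, D*W)` (or on difficulty directly, see [sim_config()]) plus a
#' subject random intercept. Failed trials are split into never-reached,
#' late-entry, and overshoot modes. All draws derive deterministically from
#' the master seed, the subject and the block.
#'
#' @param schedule a schedule from [generate_schedule()].
#' @param config the [sim_config()] used to build it.
#' @param .need_onsets internal; skip the onset check while the schedule is
#'   being built.
#' @return data.frame with one row per trial: identifiers, condition
#'   geometry, `OT`, `MT` (NA unless success), `HT`, `success`, `overshoot`,
#'   failure mode, movement-duration primitive `T_move`, implied target entry
#'   and exit times, and trial `duration`.
#' @export
simulate_trials <- function(schedule, config, .need_onsets = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  subject <- schedule$subject[1]
  cond_tab <- config$conditions
  subj <- with_seed(child_seed(config$master_seed, "subject", subject), {
    list(mt = stats::rnorm(1, 0, config$subject_intercept_sd),
         logit = stats::rnorm(1, 0, config$success_subject_sd))
  })
  res <- lapply(seq_len(nrow(schedule)), function(b) {
    cond <- cond_tab[cond_tab$condition == schedule$condition[b], ]
    n <- config$trials_per_block
    with_seed(child_seed(config$master_seed, "trials", subject, b), {
      OT <- pmax(0.03, stats::rnorm(n, config$ot_mean, config$ot_sd))
      eta <- if (config$success_model == "id") {
        config$success_id_coefs[1] + config$success_id_coefs[2] * cond$ID
      } else {
        sum(config$success_coefs * c(1, cond$D, cond$W, cond$D * cond$W))
      }
      p <- stats::plogis(eta + subj$logit)
      success <- stats::runif(n) < p
      mt_raw <- config$mt_intercept + subj$mt +
        config$mt_slope * cond$ID + stats::rnorm(n, 0, config$mt_noise_sd)
      # failure-mode draws (consumed whether or not the trial failed, to keep
      # the stream layout fixed)
      reach <- stats::runif(n) < config$fail_reach_frac
      over <- stats::runif(n) < config$overshoot_frac
      late_delay <- stats::runif(n, 0.05, 0.25)
      out <- data.frame(
        subject = subject, block = schedule$block[b],
        trial = seq_len(n), condition = cond$condition,
        D = cond$D, W = cond$W, ID = cond$ID,
        OT = OT, MT = NA_real_, HT = 0, success = success, overshoot = FALSE,
        fail_mode = "none", T_move = NA_real_,
        t_entry = NA_real_, t_exit = NA_real_, duration = NA_real_,
        stringsAsFactors = FALSE)
      for (i in seq_len(n)) {
        if (success[i]) {
          mt <- min(max(mt_raw[i], 0.05), config$trial_timeout - OT[i] - 0.01)
          out$MT[i] <- mt
          out$HT[i] <- config$hold_duration
          out$t_entry[i] <- OT[i] + mt
          out$duration[i] <- OT[i] + mt + config$hold_duration
        } else {
          out$duration[i] <- config$trial_timeout
          if (reach[i] && over[i]) {
            out$fail_mode[i] <- "overshoot"
            out$overshoot[i] <- TRUE
            tm <- min(max(mt_raw[i], 0.3), config$trial_timeout)
            ot <- overshoot_times(cond$D, cond$W, OT[i], tm, cond$W,
                                  config$start_radius)
            # keep the in-target dwell strictly below the hold requirement
            if (ot$dwell >= 0.95 * config$hold_duration) {
              tm <- tm * 0.9 * config$hold_duration / ot$dwell
              ot <- overshoot_times(cond$D, cond$W, OT[i], tm, cond$W,
                                    config$start_radius)
            }
            out$T_move[i] <- tm
            out$OT[i] <- OT[i]
            out$t_entry[i] <- ot$t_entry
            out$t_exit[i] <- ot$t_exit
            out$HT[i] <- ot$dwell
          } else if (reach[i]) {
            out$fail_mode[i] <- "late"
            out$t_entry[i] <- config$trial_timeout + late_delay[i]
          } else {
            out$fail_mode[i] <- "noreach"
          }
        }
      }
      out
    })
  })
  do.call(rbind, res)
}

#' Synthesize the 60 Hz cursor trajectory of one trial
#'
#' Builds a minimum-jerk path whose timing reproduces the trial's recorded
#' events exactly: the cursor leaves the `start_radius` zone at `OT`, and for
#' successful trials crosses the target boundary at `OT + MT`, settles at an
#' endpoint inside the target (jittered by at most `traj_jitter` of the
#' target radius towards the start; exactly the target centre when
#' `traj_jitter = 0`), and holds there. Overshoot trials fly through the
#' target to a point one width beyond its centre; late trials enter after
#' the deadline; never-reached trials stop outside the target boundary.
#' Re-classifying the result with [classify_trial()] reproduces the trial's
#' flags, and its movement time to within a kinematic sample.
#'
#' @param trial one row of the table from [simulate_trials()].
#' @param cond the matching one-row condition data.frame.
#' @param config the [sim_config()].
#' @return list with `time`, `x`, `y`, `target`, `start`, `rate`.
#' @export
simulate_trajectory <- function(trial, cond, config) {
  rate <- config$kin_rate
  t_end <- config$trial_timeout + config$hold_duration + 0.3
  t <- seq(0, t_end, by = 1 / rate)
  seed <- child_seed(config$master_seed, "traj", trial$subject, trial$block,
                     trial$trial)
  draws <- with_seed(seed, list(theta = stats::runif(1, 0, 2 * pi),
                                jit = stats::runif(1, 0, 1)))
  u <- c(cos(draws$theta), sin(draws$theta))
  start <- c(0, 0)
  target <- start + cond$D * u
  D <- cond$D; W <- cond$W; R <- config$start_radius
  path <- function(total_dist, t_go, T_move) {
    s <- mj_s((t - t_go) / T_move) * total_dist
    list(x = start[1] + s * u[1], y = start[2] + s * u[2])
  }
  mode <- if (trial$success) "success" else trial$fail_mode
  if (mode %in% c("success", "late")) {
    r_end <- if (mode == "success") draws$jit * config$traj_jitter * (W / 2)
             else 0.2 * (W / 2)
    total <- D - r_end
    tau_ot <- mj_tau(R / total)
    tau_in <- mj_tau((D - W / 2) / total)
    mt <- if (mode == "success") trial$MT else trial$t_entry - trial$OT
    T_move <- mt / (tau_in - tau_ot)
    t_go <- trial$OT - tau_ot * T_move
    p <- path(total, t_go, T_move)
  } else if (mode == "overshoot") {
    total <- D + W
    tau_ot <- mj_tau(R / total)
    T_move <- trial$T_move
    t_go <- trial$OT - tau_ot * T_move
    p <- path(total, t_go, T_move)
  } else { # noreach: stop short of the boundary
    total <- D - 0.6 * W
    tau_ot <- mj_tau(R / total)
    T_move <- config$trial_timeout
    t_go <- trial$OT - tau_ot * T_move
    p <- path(total, t_go, T_move)
  }
  list(time = t, x = p$x, y = p$y, target = target, start = start,
       rate = rate)
}

#' Simulate a subject's full behavioural session
#'
#' @param config a [sim_config()].
#' @param subject subject id.
#' @return list with `schedule` and `trials`.
#' @export
simulate_subject <- function(config, subject) {
  schedule <- generate_schedule(config, subject)
  list(schedule = schedule, trials = simulate_trials(schedule, config))
}

#' Simulate the complete multi-subject experiment (behaviour only)
#'
#' @param config a [sim_config()].
#' @return list with pooled `trials` and per-subject `schedules`.
#' @export
simulate_experiment <- function(config) {
  subs <- lapply(seq_len(config$n_subjects), function(s)
    simulate_subject(config, s))
  list(trials = do.call(rbind, lapply(subs, `[[`, "trials")),
       schedules = lapply(subs, `[[`, "schedule"))
}
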