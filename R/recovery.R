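# Parameter-recovery experiments: regenerate the behavioural experiment many
# times and refit the mixed models, to check that the estimation chain
# returns the generating parameters.

#' Simulate the behavioural part of an experiment (trials only)
#'
#' @param config a [sim_config()].
#' @return pooled trial table across subjects.
#' @export
simulate_behavior <- function(config) {
  do.call(rbind, lapply(seq_len(config$n_subjects), function(s)
    simulate_trials(generate_schedule(config, s), config)))
}

#' Recover the Fitts-law movement-time slope over replicates
#'
#' Repeatedly simulates the full behavioural experiment (default: 16
#' subjects x 12 blocks x 15 trials, subject-intercept SD 0.1 s, residual SD
#' 0.15 s) with the configured generating slope, fits
#' `MT ~ ID + (1 | subject)` by REML on the successful trials, and collects
#' the fixed-effect slope and its standard error.
#'
#' @param n_rep number of replicates.
#' @param seed integer seed; replicate seeds derive from it.
#' @param config base [sim_config()]; `master_seed` is overridden per
#'   replicate.
#' @return data.frame: `rep`, `estimate`, `se`, plus attribute `truth`
#'   (the generating slope).
#' @export
recover_mt_slope <- function(n_rep = 50, seed = 1, config = sim_config()) {
  out <- lapply(seq_len(n_rep), function(r) {
    config$master_seed <- child_seed(seed, "mt-recovery", r)
    trials <- simulate_behavior(config)
    fit <- fit_lmm(MT ~ ID + (1 | subject), trials[trials$success, ])
    i <- match("ID", fit$coefficients$term)
    data.frame(rep = r, estimate = fit$coefficients$estimate[i],
               se = fit$coefficients$se[i])
  })
  structure(do.call(rbind, out), truth = config$mt_slope)
}

#' Recover the logistic difficulty coefficient over replicates
#'
#' Repeatedly simulates binary success outcomes with
#' `logit = intercept + b * ID + subject effect` (subject SD 0.5 by default)
#' and refits the random-intercept logistic model by Laplace-approximated
#' maximum likelihood, collecting the fitted `b`.
#'
#' @inheritParams recover_mt_slope
#' @return data.frame: `rep`, `estimate`, `se`; attribute `truth` holds the
#'   generating coefficient.
#' @export
recover_success_coef <- function(n_rep = 50, seed = 1,
                                 config = sim_config(success_model = "id")) {
  out <- lapply(seq_len(n_rep), function(r) {
    config$master_seed <- child_seed(seed, "succ-recovery", r)
    trials <- simulate_behavior(config)
    fit <- fit_glmm_logistic(success ~ ID + (1 | subject), trials)
    i <- match("ID", fit$coefficients$term)
    data.frame(rep = r, estimate = fit$coefficients$estimate[i],
               se = fit$coefficients$se[i])
  })
  structure(do.call(rbind, out), truth = config$success_id_coefs[2])
}
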