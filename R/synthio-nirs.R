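# Synthetic probe registration and 10 Hz oxy-Hb hemodynamics.

#' Probe registration of the reference subject
#'
#' The measured channel-to-anatomy registration of subject 04: channel id,
#' most-likely Brodmann area (4 = primary motor, 6 = premotor/SMA),
#' hemisphere, MNI coordinate and registration probability. Covers the 11
#' left-hemisphere motor channels with measured registrations.
#'
#' @return data.frame with columns `channel`, `ba_label`, `hemisphere`,
#'   `mni_x`, `mni_y`, `mni_z`, `probability`.
#' @export
s04_registration <- function() {
  read_registration(system.file("extdata", "s04_registration.csv",
                                package = "fittsnirs", mustWork = TRUE))
}

#' Generate a full 44-channel probabilistic registration table
#'
#' Embeds the measured rows of [s04_registration()] verbatim and fills the
#' remaining channels synthetically: Brodmann label and hemisphere follow the
#' probe's ROI channel sets ([roi_channels()]; left hemisphere is
#' contralateral to the moving right hand), registration probabilities are
#' drawn uniformly on (0.45, 1), and MNI coordinates are jittered around
#' motor-strip locations (mirrored across the midline for the ipsilateral
#' side). The synthetic rows are placeholders for measured digitizer output,
#' not anatomical ground truth.
#'
#' @param config a [sim_config()]; only the master seed is used.
#' @return data.frame with one row per channel 1..44, same columns as
#'   [s04_registration()].
#' @export
generate_registration <- function(config) {
  fix <- s04_registration()
  rois <- roi_channels()
  ba <- rep(6L, 44)
  ba[c(rois$contra_BA4, rois$ipsi_BA4)] <- 4L
  hemi <- rep(NA_character_, 44)
  hemi[c(rois$contra_BA4, rois$contra_BA6)] <- "L"
  hemi[c(rois$ipsi_BA4, rois$ipsi_BA6)] <- "R"
  hemi[1:8] <- rep(c("R", "L"), each = 4) # frontal row outside the ROIs
  with_seed(child_seed(config$master_seed, "registration"), {
    reg <- data.frame(
      channel = 1:44, ba_label = ba, hemisphere = hemi,
      mni_x = ifelse(hemi == "L", -1, 1) * stats::runif(44, 5, 55),
      mni_y = stats::runif(44, -40, 25),
      mni_z = stats::runif(44, 50, 80),
      probability = stats::runif(44, 0.45, 1),
      stringsAsFactors = FALSE)
    reg[fix$channel, ] <- fix
    reg
  })
}

#' Simulate a subject's 44-channel oxy-Hb recording
#'
#' Per channel, the 10 Hz series is the sum of (i) the task response: each
#' condition's block boxcar convolved with the canonical double-gamma HRF
#' (peak-normalized, identical to the regressors of [build_design()]) scaled
#' by the channel's true amplitude in `beta_map`; (ii) a constant device
#' baseline and a linear drift; (iii) sinusoidal physiological oscillations
#' (Mayer wave, respiration, cardiac) with channel-specific random phases;
#' (iv) Poisson-arriving motion artifacts (single-sample spikes and sustained
#' baseline shifts); and (v) white Gaussian noise. The record starts at
#' `t = 0`, one rest period before the first block, so every block has at
#' least 5 s of pre-onset baseline.
#'
#' @param schedule a [generate_schedule()] table.
#' @param config the [sim_config()].
#' @return object of class `nirs_series`: list with `subject`, `time`,
#'   `rate`, and the n-samples x 44 `data` matrix (columns `ch01`..`ch44`).
#' @export
simulate_hemodynamics <- function(schedule, config) {
  rate <- config$nirs_rate
  session_end <- schedule$onset[nrow(schedule)] +
    schedule$duration[nrow(schedule)] + config$rest_duration
  n <- ceiling(session_end * rate) + 1
  t <- (seq_len(n) - 1) / rate
  X <- build_design(schedule, n, rate,
                    conditions = config$conditions$condition)
  # n x 44 task response; beta_map columns reordered to the design's columns
  task <- X$matrix[, X$condition_cols, drop = FALSE] %*%
    t(config$beta_map[, X$conditions, drop = FALSE])
  data <- matrix(0, n, 44, dimnames = list(NULL, sprintf("ch%02d", 1:44)))
  for (ch in 1:44) {
    sig <- with_seed(child_seed(config$master_seed, "nirs",
                                schedule$subject[1], ch), {
      s <- config$channel_baseline + config$drift_slope * t + task[, ch]
      for (of in config$osc_amps_freqs)
        s <- s + of[1] * sin(2 * pi * of[2] * t + stats::runif(1, 0, 2 * pi))
      n_art <- stats::rpois(1, config$artifact_rate * session_end / 60)
      if (n_art > 0) {
        at <- sample.int(n, n_art)
        spike <- stats::runif(n_art) < 0.5
        amp <- sample(c(-1, 1), n_art, replace = TRUE) *
          config$noise_sd *
          ifelse(spike, config$artifact_spike_gain, config$artifact_shift_gain)
        for (k in seq_len(n_art)) {
          if (spike[k]) s[at[k]] <- s[at[k]] + amp[k]
          else s[at[k]:n] <- s[at[k]:n] + amp[k]
        }
      }
      s + stats::rnorm(n, 0, config$noise_sd)
    })
    data[, ch] <- sig
  }
  structure(list(subject = schedule$subject[1], time = t, rate = rate,
                 data = data), class = "nirs_series")
}

#' @export
print.nirs_series <- function(x, ...) {
  cat(sprintf("nirs_series: subject %s, %d channels x %d samples at %g Hz\n",
              x$subject, ncol(x$data), nrow(x$data), x$rate))
  invisible(x)
}
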