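test_that("schedules permute conditions with the study's block structure", {
  cfg <- sim_config(master_seed = 123)
  sc <- generate_schedule(cfg, 1)
  expect_equal(nrow(sc), 12)
  expect_equal(sort(as.numeric(table(sc$condition))), c(3, 3, 3, 3))
  expect_true(all(diff(sc$onset) > 0))
  # inter-block gap equals the rest duration
  gaps <- sc$onset[-1] - (sc$onset + sc$duration)[-12]
  expect_equal(gaps, rep(cfg$rest_duration, 11))
  expect_equal(sc$onset[1], cfg$rest_duration)
  # block duration equals the sum of its trials' durations
  tr <- simulate_trials(sc, cfg)
  durs <- as.numeric(tapply(tr$duration, tr$block, sum))
  expect_equal(durs, sc$duration, tolerance = 1e-12)
})

test_that("schedule generation is deterministic and respects rep counts", {
  cfg <- sim_config(master_seed = 5)
  expect_identical(generate_schedule(cfg, 3), generate_schedule(cfg, 3))
  expect_false(identical(generate_schedule(cfg, 3)$condition,
                         generate_schedule(cfg, 4)$condition))
  cfg1 <- sim_config(reps_per_condition = 1)
  sc1 <- generate_schedule(cfg1, 1)
  expect_equal(nrow(sc1), 4)
  expect_equal(sort(sc1$condition), sort(cfg1$conditions$condition))
  expect_error(sim_config(trials_per_block = 0), "positive")
  expect_error(sim_config(rest_duration = -1), "> 0")
})

test_that("noise-free trials sit exactly on the Fitts line", {
  cfg <- sim_config(mt_noise_sd = 0, subject_intercept_sd = 0, master_seed = 2)
  sc <- generate_schedule(cfg, 1)
  tr <- simulate_trials(sc, cfg)
  ok <- tr$success
  expect_equal(tr$MT[ok], cfg$mt_intercept + cfg$mt_slope * tr$ID[ok],
               tolerance = 1e-12)
})

test_that("success outcomes follow the logistic model (Monte Carlo)", {
  # one condition, many trials; compare against the closed-form probability
  cfg <- sim_config(n_subjects = 1, success_subject_sd = 0,
                    trials_per_block = 250, reps_per_condition = 10,
                    conditions = task_condition(600, 40), master_seed = 31)
  sc <- generate_schedule(cfg, 1)
  tr <- simulate_trials(sc, cfg)
  co <- cfg$success_coefs
  p <- stats::plogis(sum(co * c(1, 600, 40, 600 * 40)))
  mc_sd <- sqrt(p * (1 - p) / nrow(tr))
  expect_equal(nrow(tr), 2500)
  expect_lt(abs(mean(tr$success) - p), 3 * mc_sd)
})

test_that("an overwhelming success logit makes every trial a success", {
  cfg <- sim_config(n_subjects = 1, success_model = "id",
                    success_id_coefs = c(100, 0), master_seed = 9)
  tr <- simulate_trials(generate_schedule(cfg, 1), cfg)
  expect_true(all(tr$success))
})

test_that("trajectories reproduce their trial's classification exactly", {
  cfg <- sim_config(n_subjects = 4, master_seed = 77)
  mism <- 0; mt_err <- 0; modes <- character(0)
  for (s in 1:4) {
    sc <- generate_schedule(cfg, s)
    tr <- simulate_trials(sc, cfg)
    for (i in seq_len(nrow(tr))) {
      trial <- tr[i, ]
      cond <- cfg$conditions[cfg$conditions$condition == trial$condition, ]
      traj <- simulate_trajectory(trial, cond, cfg)
      cl <- classify_trial(traj, cond, cfg$trial_timeout, cfg$hold_duration,
                           cfg$start_radius)
      if (cl$success != trial$success || cl$overshoot != trial$overshoot)
        mism <- mism + 1
      if (trial$success) mt_err <- max(mt_err, abs(cl$MT - trial$MT))
      modes <- c(modes, trial$fail_mode)
    }
  }
  expect_equal(mism, 0)
  expect_lt(mt_err, 1 / cfg$kin_rate)          # within one kinematic sample
  # all three failure modes were exercised
  expect_true(all(c("overshoot", "late", "noreach") %in% modes))
})

test_that("zero endpoint jitter lands successful reaches on the target centre", {
  cfg <- sim_config(n_subjects = 1, traj_jitter = 0, master_seed = 12)
  sc <- generate_schedule(cfg, 1)
  tr <- simulate_trials(sc, cfg)
  trial <- tr[which(tr$success)[1], ]
  cond <- cfg$conditions[cfg$conditions$condition == trial$condition, ]
  traj <- simulate_trajectory(trial, cond, cfg)
  endpoint <- c(traj$x[length(traj$x)], traj$y[length(traj$y)])
  expect_equal(endpoint, traj$target, tolerance = 1e-9)
})

test_that("never-reached failures stay outside the target disc", {
  cfg <- sim_config(n_subjects = 2, master_seed = 55)
  found <- FALSE
  for (s in 1:2) {
    sc <- generate_schedule(cfg, s)
    tr <- simulate_trials(sc, cfg)
    for (i in which(tr$fail_mode == "noreach")) {
      trial <- tr[i, ]
      cond <- cfg$conditions[cfg$conditions$condition == trial$condition, ]
      traj <- simulate_trajectory(trial, cond, cfg)
      d <- sqrt((traj$x - traj$target[1])^2 + (traj$y - traj$target[2])^2)
      expect_gt(min(d), cond$W / 2)
      found <- TRUE
    }
  }
  expect_true(found)
})

test_that("hemodynamic series are bit-identical under the same seed", {
  cfg <- sim_config(n_subjects = 1, master_seed = 88)
  sc <- generate_schedule(cfg, 1)
  expect_identical(simulate_hemodynamics(sc, cfg),
                   simulate_hemodynamics(sc, cfg))
  cfg2 <- sim_config(n_subjects = 1, master_seed = 89)
  expect_false(identical(simulate_hemodynamics(sc, cfg)$data,
                         simulate_hemodynamics(sc, cfg2)$data))
})

test_that("trial counts are conserved: blocks x trials_per_block", {
  cfg <- sim_config(n_subjects = 1, trials_per_block = 7,
                    reps_per_condition = 2, master_seed = 4)
  tr <- simulate_trials(generate_schedule(cfg, 1), cfg)
  expect_equal(nrow(tr), 8 * 7)
})

test_that("registration embeds the measured subject-04 rows verbatim", {
  reg <- generate_registration(sim_config())
  expect_equal(nrow(reg), 44)
  expect_true(all(reg$probability > 0 & reg$probability <= 1))
  expect_equal(reg$probability[reg$channel == 32], 1)
  expect_equal(reg$ba_label[reg$channel == 32], 6)
  expect_equal(reg$probability[reg$channel == 14], 0.756)
  expect_equal(reg$ba_label[reg$channel == 14], 4)
  fix <- s04_registration()
  expect_equal(reg[fix$channel, ], fix, ignore_attr = TRUE)
  # every ROI has at least 3 registered channels
  for (roi in names(roi_channels())) {
    hemi <- if (startsWith(roi, "contra")) "L" else "R"
    ba <- as.integer(sub(".*_BA", "", roi))
    expect_gte(sum(reg$hemisphere == hemi & reg$ba_label == ba), 3)
  }
})

test_that("child seeds are stable and stream-separating", {
  expect_identical(child_seed(42, "trials", 3, 7), child_seed(42, "trials", 3, 7))
  expect_false(child_seed(42, "trials", 3, 7) == child_seed(42, "trials", 3, 8))
  expect_false(child_seed(42, "nirs", 3) == child_seed(42, "traj", 3))
  s <- child_seed(2^31 - 10, "x", 999)
  expect_true(s >= 0 && s < 2^31)
})

test_that("YAML configuration files mirror sim_config fields", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 3",
               "mt_slope: 0.25",
               "master_seed: 99",
               "conditions:",
               "  - {D: 300, W: 50}",
               "  - {D: 500, W: 100}"), tmp)
  cfg <- sim_config_from_yaml(tmp)
  expect_equal(cfg$n_subjects, 3)
  expect_equal(cfg$mt_slope, 0.25)
  expect_equal(nrow(cfg$conditions), 2)
  expect_equal(cfg$conditions$ID[1], index_of_difficulty(300, 50))
  expect_equal(cfg$rest_duration, 20)      # defaults retained
  writeLines("nonsense_field: 1", tmp)
  expect_error(sim_config_from_yaml(tmp), "unknown field")
})
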