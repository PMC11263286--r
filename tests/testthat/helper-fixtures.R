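# Shared fixtures, generated in code at test time.

# straight-line trajectory that enters the target at a known time and stays
make_straight_traj <- function(enter_at, D = 200, W = 120, rate = 60,
                               t_end = 3, exit_at = NULL, speed_start = 0.1) {
  t <- seq(0, t_end, by = 1 / rate)
  start <- c(0, 0); target <- c(D, 0)
  # piecewise-linear distance profile: wait, move, (optionally exit again)
  enter_d <- D - W / 2
  x <- numeric(length(t))
  move_t0 <- speed_start            # leaves start zone shortly after this
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= move_t0) x[i] <- 0
    else if (ti <= enter_at) {
      x[i] <- enter_d * (ti - move_t0) / (enter_at - move_t0)
    } else if (is.null(exit_at)) {
      x[i] <- min(D, enter_d + 20 * (ti - enter_at))
    } else if (ti <= exit_at) {
      # traverse the target disc, reaching the far boundary at exit_at
      x[i] <- enter_d + W * (ti - enter_at) / (exit_at - enter_at)
    } else {
      x[i] <- enter_d + W + 50 * (ti - exit_at)
    }
  }
  list(time = t, x = x, y = rep(0, length(t)), target = target,
       start = start, rate = rate)
}

# random-intercept gaussian data on the Fitts line
make_lmm_data <- function(seed, J = 16, nper = 60, slope = 0.3,
                          intercept = 0.1, sd_subj = 0.1, sd_res = 0.15) {
  set.seed(seed)
  d <- data.frame(subject = rep(seq_len(J), each = nper),
                  ID = sample(c(1.737, 3.322, 3.322, 4.907), J * nper, TRUE))
  b <- stats::rnorm(J, 0, sd_subj)
  d$MT <- intercept + slope * d$ID + b[d$subject] +
    stats::rnorm(nrow(d), 0, sd_res)
  d
}

# random-intercept binary data on the difficulty logit
make_glmm_data <- function(seed, J = 16, nper = 180, intercept = 8,
                           slope = -1.3407, sd_subj = 0.5) {
  set.seed(seed)
  d <- data.frame(subject = rep(seq_len(J), each = nper),
                  ID = sample(c(1.737, 3.322, 3.322, 4.907), J * nper, TRUE))
  b <- stats::rnorm(J, 0, sd_subj)
  d$success <- stats::runif(nrow(d)) <
    stats::plogis(intercept + slope * d$ID + b[d$subject])
  d
}

# small clean block-design oxy-Hb signal plus its design
make_clean_signal <- function(n_sec = 600, rate = 10, amps = c(0.03, 0.02)) {
  n <- n_sec * rate + 1
  ev <- data.frame(onset = seq(20, n_sec - 40, by = 45), duration = 25,
                   condition = rep(c("A", "B"),
                                   length.out = length(seq(20, n_sec - 40,
                                                           by = 45))))
  X <- build_design(ev, n, rate)
  y <- as.numeric(X$matrix[, X$condition_cols, drop = FALSE] %*%
                    amps[seq_along(X$condition_cols)])
  list(y = y, events = ev, design = X, n = n, rate = rate)
}

rms <- function(x) sqrt(mean(x^2))

make_tempdir <- function() {
  d <- tempfile("fittsnirs-test-")
  dir.create(d)
  d
}
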