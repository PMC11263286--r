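# Fitts-law kinematic measures and trial classification.

#' Index of difficulty of a reaching condition
#'
#' Fitts' original formulation `ID = log2(2 D / W)` in bits, where `D` is the
#' centre-to-centre target distance and `W` the target width (disc diameter).
#' This form reproduces the printed difficulty levels of the 2x2 design used
#' throughout the package (1.74, 3.32 and 4.91 bits); the Shannon variant
#' `log2(D/W + 1)` does not.
#'
#' @param D target distance, pixels (> 0). Vectorised.
#' @param W target width (disc diameter), pixels (> 0). Vectorised.
#' @return index of difficulty in bits.
#' @examples
#' index_of_difficulty(200, 120) # 1.74 bits
#' index_of_difficulty(600, 40)  # 4.91 bits
#' @export
index_of_difficulty <- function(D, W) {
  if (any(D <= 0) || any(W <= 0))
    stop_domain("index_of_difficulty: D and W must be positive (got D=%s, W=%s)",
                toString(D), toString(W))
  log2(2 * D / W)
}

#' Convert screen pixels to workspace centimetres
#'
#' The task screen maps linearly onto the robot workspace, so one pixel
#' corresponds to `workspace_cm / screen_px` centimetres (0.0271 cm for a
#' 52 cm workspace shown across 1920 px).
#'
#' @param v value in pixels (vectorised).
#' @param workspace_cm workspace extent in cm along the same axis (> 0).
#' @param screen_px screen resolution in pixels along that axis (> 0).
#' @return `v` expressed in centimetres.
#' @export
px_to_cm <- function(v, workspace_cm = 52, screen_px = 1920) {
  if (workspace_cm <= 0 || screen_px <= 0)
    stop_domain("px_to_cm: workspace_cm and screen_px must be positive")
  v * workspace_cm / screen_px
}

#' Task condition constructor
#'
#' @param D distance, px. @param W width, px.
#' @return data.frame with columns `condition`, `D`, `W`, `ID`.
#' @export
task_condition <- function(D, W) {
  data.frame(condition = sprintf("D%dW%d", as.integer(D), as.integer(W)),
             D = D, W = W, ID = index_of_difficulty(D, W),
             stringsAsFactors = FALSE)
}

# Linearly interpolated time at which a sampled series `y` first crosses
# `level` in the given direction, or NA if it never does.
first_crossing <- function(t, y, level, upward = TRUE) {
  if (!upward) { y <- -y; level <- -level }
  above <- y > level
  if (above[1]) return(t[1])
  i <- which(above)[1]
  if (is.na(i)) return(NA_real_)
  # crossing between i-1 and i
  frac <- (level - y[i - 1]) / (y[i] - y[i - 1])
  t[i - 1] + frac * (t[i] - t[i - 1])
}

# All maximal inside-target intervals of the distance series `d` (distance to
# target centre) against radius `r`, with linear interpolation of boundary
# crossing times. Returns data.frame(t_in, t_out); an interval still open at
# the end of the record gets t_out = t[length(t)].
inside_intervals <- function(t, d, r) {
  inside <- d <= r
  n <- length(t)
  if (!any(inside)) return(data.frame(t_in = numeric(0), t_out = numeric(0)))
  x <- c(FALSE, inside, FALSE)
  starts <- which(diff(x) == 1L)       # first inside sample of each run
  ends <- which(diff(x) == -1L) - 1L   # last inside sample of each run
  t_in <- vapply(starts, function(i) {
    if (i == 1L) t[1] else {
      frac <- (r - d[i - 1]) / (d[i] - d[i - 1])
      t[i - 1] + frac * (t[i] - t[i - 1])
    }
  }, numeric(1))
  t_out <- vapply(ends, function(i) {
    if (i == n) t[n] else {
      frac <- (r - d[i]) / (d[i + 1] - d[i])
      t[i] + frac * (t[i + 1] - t[i])
    }
  }, numeric(1))
  data.frame(t_in = t_in, t_out = t_out)
}

#' Classify a cursor trajectory into a trial record
#'
#' Applies the success / failure / overshoot taxonomy of the reaching task:
#' a trial succeeds when the cursor centre enters the target disc (Euclidean
#' distance to the target centre at most `W/2`) no later than `timeout`
#' seconds after target appearance and then remains inside continuously for
#' at least `hold` seconds (the hold may complete after the deadline). A
#' trial that entered the target but never stayed for `hold` is an overshoot.
#' Onset time `OT` is the moment the cursor first leaves the start zone;
#' movement time `MT` (successes only) runs from `OT` to the qualifying entry.
#' Boundary crossing times are refined by linear interpolation between the
#' 60 Hz samples.
#'
#' @param traj list with `time` (seconds), `x`, `y` (px), `target` c(x, y),
#'   `start` c(x, y), as produced by [simulate_trajectory()].
#' @param cond one-row data.frame from [task_condition()].
#' @param timeout entry deadline, seconds.
#' @param hold required continuous in-target time, seconds.
#' @param start_radius radius of the start zone used for OT detection, px.
#' @param cursor_radius radius of the cursor disc, px. The default 0 treats
#'   the cursor as a point; setting it to the drawn cursor's radius (10 px)
#'   counts a trial as inside once the discs overlap.
#' @return one-row data.frame: `OT`, `MT` (NA unless success), `HT`,
#'   `success`, `overshoot`.
#' @export
classify_trial <- function(traj, cond, timeout = 2, hold = 0.5,
                           start_radius = 10, cursor_radius = 0) {
  t <- traj$time
  if (t[length(t)] < timeout + hold)
    stop_domain("classify_trial: trajectory must cover [0, timeout + hold]")
  d_target <- sqrt((traj$x - traj$target[1])^2 + (traj$y - traj$target[2])^2)
  d_start <- sqrt((traj$x - traj$start[1])^2 + (traj$y - traj$start[2])^2)
  OT <- first_crossing(t, d_start, start_radius, upward = TRUE)
  iv <- inside_intervals(t, d_target, cond$W / 2 + cursor_radius)
  dur <- iv$t_out - iv$t_in
  qual <- which(iv$t_in <= timeout & dur >= hold)
  success <- length(qual) > 0
  if (success) {
    MT <- iv$t_in[qual[1]] - OT
    HT <- dur[qual[1]]
    overshoot <- FALSE
  } else {
    MT <- NA_real_
    HT <- if (nrow(iv)) max(dur) else 0
    overshoot <- nrow(iv) > 0 && all(dur < hold)
  }
  data.frame(OT = OT, MT = MT, HT = HT, success = success,
             overshoot = overshoot)
}

#' Throughput over a set of trials
#'
#' Mean rate of information transmission `TP = (1/N) * sum(ID_i / MT_i)` over
#' the `N` successful trials, in bits per second.
#'
#' @param trials data.frame with columns `ID`, `MT`, `success`.
#' @return list with `TP` (bit/s) and `N` (number of successful trials).
#' @export
throughput <- function(trials) {
  ok <- trials$success & !is.na(trials$MT)
  if (!any(ok)) stop_domain("throughput: no successful trials")
  list(TP = mean(trials$ID[ok] / trials$MT[ok]), N = sum(ok))
}

#' Percentage of overshot trials
#'
#' @param trials data.frame with logical column `overshoot`.
#' @return percentage in `[0, 100]`.
#' @export
overshoot_rate <- function(trials) {
  if (nrow(trials) == 0) stop_domain("overshoot_rate: empty trial list")
  100 * sum(trials$overshoot) / nrow(trials)
}

#' Per-condition kinematic summary
#'
#' @param trials trial table (possibly several subjects).
#' @return data.frame per condition: success %, overshoot %, MT mean/sd,
#'   throughput.
#' @export
kinematic_summary <- function(trials) {
  do.call(rbind, lapply(split(trials, trials$condition), function(d) {
    tp <- if (any(d$success)) throughput(d)$TP else NA_real_
    data.frame(condition = d$condition[1], D = d$D[1], W = d$W[1],
               ID = d$ID[1], n_trials = nrow(d),
               success_pct = 100 * mean(d$success),
               overshoot_pct = overshoot_rate(d),
               MT_mean = mean(d$MT[d$success], na.rm = TRUE),
               MT_sd = stats::sd(d$MT[d$success]),
               TP = tp, row.names = NULL)
  }))
}
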