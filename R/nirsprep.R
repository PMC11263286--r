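# Oxy-Hb preprocessing: linear detrend -> TDDR -> zero-phase Butterworth
# band-pass, channel quality exclusion, baseline-referenced block activation.

#' Preprocessing parameters
#'
#' @param band band-pass cut-offs in Hz, default `c(0.01, 0.08)` (retains the
#'   task-locked hemodynamic band; removes drift below and Mayer wave,
#'   respiration and cardiac oscillations above).
#' @param filter_order Butterworth order (applied forward and backward, so
#'   the effective attenuation doubles in dB).
#' @param cv_threshold coefficient-of-variation exclusion threshold, percent,
#'   evaluated on the unprocessed series.
#' @param baseline_window pre-onset baseline window, seconds.
#' @param tddr_trend_window running-median trend window for [tddr()],
#'   seconds (default 1).
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(band = c(0.01, 0.08), filter_order = 3,
                              cv_threshold = 30, baseline_window = 5,
                              tddr_trend_window = 1) {
  if (band[1] <= 0 || band[2] <= band[1])
    stop_domain("preprocess_params: need 0 < low < high")
  if (filter_order < 1) stop_domain("preprocess_params: order >= 1")
  if (cv_threshold <= 0) stop_domain("preprocess_params: cv_threshold > 0")
  structure(list(band = band, filter_order = filter_order,
                 cv_threshold = cv_threshold,
                 baseline_window = baseline_window,
                 tddr_trend_window = tddr_trend_window),
            class = "preprocess_params")
}

#' Remove the least-squares linear trend from a series
#'
#' @param x numeric vector (>= 2 samples).
#' @return detrended vector (zero mean, orthogonal to a linear ramp).
#' @export
linear_detrend <- function(x) {
  n <- length(x)
  if (n < 2) stop_domain("linear_detrend: need at least 2 samples")
  tt <- seq_len(n) - (n + 1) / 2           # centred time, orthogonal to 1
  b <- sum(tt * x) / sum(tt * tt)
  x - mean(x) - b * tt
}

#' Temporal derivative distribution repair (TDDR)
#'
#' Robust motion-artifact correction operating on the temporal derivative of
#' the signal. The derivative is decomposed into a robust local trend (a
#' `trend_window`-second running median), which carries the smooth
#' hemodynamic variation, plus residuals, which carry measurement noise and
#' the impulsive derivative excursions produced by motion: a spike is a pair
#' of large opposite-signed derivative residuals, a baseline shift a single
#' one. A robust location and scale of the residuals are estimated by
#' iteratively reweighted least squares with Tukey's biweight (c = 4.685,
#' MAD scale) until the weights converge; residuals beyond the biweight
#' rejection point (where the weight function reaches zero) are then
#' replaced by the local trend plus the robust location, and the corrected
#' derivative is cumulatively re-integrated.
#'
#' Inlier derivatives are passed through exactly, so artifact-free signals
#' are essentially unchanged (a constant series exactly so) and no
#' reintegration drift is injected, while spike and shift artifacts, whose
#' derivative residuals are gross outliers relative to the residual scale,
#' are suppressed. Artifacts smaller than the rejection point relative to
#' the noise floor are deliberately left for the subsequent band-pass.
#'
#' @param x numeric vector (>= 10 samples).
#' @param rate sampling rate, Hz.
#' @param trend_window width of the derivative's running-median trend,
#'   seconds (default 1).
#' @param tol convergence tolerance on the robust-weight change.
#' @param max_iter iteration cap.
#' @return corrected vector, same length.
#' @export
tddr <- function(x, rate = 10, trend_window = 1, tol = 1e-6, max_iter = 50) {
  n <- length(x)
  if (n < 10) stop_domain("tddr: series shorter than 10 samples")
  d <- diff(x)
  k <- min(max(3, 2 * floor(trend_window * rate / 2) + 1), length(d))
  if (k %% 2 == 0) k <- k - 1
  trend <- stats::runmed(d, k, endrule = "median")
  res <- d - trend
  w <- rep(1, length(res))
  mu <- 0
  r <- rep(0, length(res))
  for (iter in seq_len(max_iter)) {
    w_old <- w
    mu <- sum(w * res) / sum(w)
    dev <- res - mu
    sigma <- 1.4826 * stats::median(abs(dev))
    if (sigma <= .Machine$double.eps * max(1, abs(mu)))
      break                     # no measurable dispersion: nothing to repair
    r <- dev / (4.685 * sigma)
    w <- ((1 - r^2) * (abs(r) < 1))^2
    if (sum(w) == 0) { w <- w_old; break }
    if (max(abs(w - w_old)) < tol) break
  }
  d_corr <- d
  reject <- abs(r) >= 1
  # a spike is a cancelling pair of derivative outliers: pull in an adjacent
  # opposite-signed near-outlier so the event is repaired as one unit
  idx <- which(reject)
  for (j in idx) for (nb in c(j - 1, j + 1)) {
    if (nb >= 1 && nb <= length(d) && !reject[nb] &&
        abs(r[nb]) > 0.5 && sign(res[nb] - mu) != sign(res[j] - mu) &&
        abs((res[j] - mu) + (res[nb] - mu)) < 0.5 * abs(res[j] - mu))
      reject[nb] <- TRUE
  }
  # Repair rejected runs. A run is treated as a baseline shift only when the
  # signal level genuinely moves across the event (medians over 1-s windows
  # on either side agree in sign and size with the run's net derivative);
  # then its net is removed. Otherwise the run is impulse-like: its net is
  # preserved while the cancelling excursion is flattened, so no spurious
  # baseline step can ever be injected (a single-sample run degenerates to a
  # no-op).
  wlev <- k
  rr <- rle(reject)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1
  for (q in which(rr$values)) {
    run <- starts[q]:ends[q]
    resc <- res[run] - mu
    net <- sum(resc)
    base <- trend[run] + mu
    before <- x[max(1, starts[q] - wlev):starts[q]]
    after <- x[min(n, ends[q] + 2):min(n, ends[q] + 1 + wlev)]
    jump <- stats::median(after) - stats::median(before)
    # a shift's net derivative must itself be outlier-sized AND show up as a
    # sustained level change; otherwise the event is impulse-like
    is_shift <- abs(net) > 4.685 * sigma &&
      sign(jump) == sign(net) && abs(jump) > 0.5 * abs(net)
    d_corr[run] <- if (is_shift) base else base + net / length(run)
  }
  cumsum(c(x[1], d_corr))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order (by default) Butterworth band-pass applied forward and
#' backward ([signal::filtfilt()]), so the phase response is zero and the
#' magnitude response is the squared single-pass response.
#'
#' @param x numeric vector.
#' @param rate sampling rate, Hz.
#' @param band `c(low, high)` cut-offs in Hz; must be below the Nyquist rate.
#' @param order filter order.
#' @return filtered vector, same length.
#' @export
bandpass <- function(x, rate = 10, band = c(0.01, 0.08), order = 3) {
  if (band[2] >= rate / 2)
    stop_domain("bandpass: band must lie below the Nyquist frequency %g Hz",
                rate / 2)
  bf <- signal::butter(order, band * 2 / rate, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic magnitude response of the band-pass filter
#'
#' Evaluates `|H(f)|^passes` of the Butterworth band-pass used by
#' [bandpass()]; with `passes = 2` this is the effective zero-phase response.
#'
#' @param f frequencies, Hz (vectorised).
#' @inheritParams bandpass
#' @param passes number of filter passes (2 for filtfilt).
#' @return gain at each frequency.
#' @export
filter_gain <- function(f, rate = 10, band = c(0.01, 0.08), order = 3,
                        passes = 2) {
  bf <- signal::butter(order, band * 2 / rate, type = "pass")
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / rate * seq(0, length(bf$b) - 1))
    abs(sum(bf$b * z) / sum(bf$a * z))^passes
  }, numeric(1))
}

#' Coefficient of variation of a raw channel
#'
#' `CV = 100 * SD / |mean|`, computed on the unprocessed series (after
#' detrending or band-passing the mean is forced towards zero and a CV is
#' meaningless).
#'
#' @param x numeric vector.
#' @return CV in percent; `Inf` when the mean is zero.
#' @export
channel_cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(Inf)
  100 * stats::sd(x) / abs(m)
}

#' Select channels below the coefficient-of-variation threshold
#'
#' @param cvs named numeric vector of per-channel CVs (percent).
#' @param threshold exclusion threshold, percent.
#' @return list: `keep` (logical vector), `excluded` (names), `cvs`.
#' @export
exclude_channels <- function(cvs, threshold = 30) {
  keep <- is.finite(cvs) & cvs <= threshold
  list(keep = keep, excluded = names(cvs)[!keep], cvs = cvs)
}

#' Apply the full preprocessing chain to one channel
#'
#' Fixed order: (1) linear detrend, (2) TDDR, (3) zero-phase Butterworth
#' band-pass.
#'
#' @param x numeric vector.
#' @param rate sampling rate, Hz.
#' @param params a [preprocess_params()].
#' @return processed vector with attribute `steps` recording the applied
#'   stages in order.
#' @export
preprocess_channel <- function(x, rate, params = preprocess_params()) {
  out <- linear_detrend(x)
  out <- tddr(out, rate, trend_window = params$tddr_trend_window)
  out <- bandpass(out, rate, params$band, params$filter_order)
  attr(out, "steps") <- c("linear_detrend", "tddr", "bandpass")
  out
}

#' Preprocess a multi-channel recording
#'
#' Computes raw-channel CVs, drops channels above the exclusion threshold,
#' and runs [preprocess_channel()] on the retained ones. The first and last
#' `1 / band[1]` seconds are flagged as filter edge regions in the metadata.
#'
#' @param series a `nirs_series` from [simulate_hemodynamics()] (or
#'   [read_series()]).
#' @param params a [preprocess_params()].
#' @return a `nirs_series` whose `data` holds the retained, processed
#'   channels, plus `cvs`, `excluded`, `edge_seconds` and `steps` fields.
#' @export
preprocess_series <- function(series, params = preprocess_params()) {
  cvs <- apply(series$data, 2, channel_cv)
  sel <- exclude_channels(cvs, params$cv_threshold)
  if (length(sel$excluded))
    warning(sprintf("excluding %d channel(s) with CV > %g%%: %s",
                    length(sel$excluded), params$cv_threshold,
                    paste(sel$excluded, collapse = ", ")))
  proc <- apply(series$data[, sel$keep, drop = FALSE], 2,
                preprocess_channel, rate = series$rate, params = params)
  structure(list(subject = series$subject, time = series$time,
                 rate = series$rate, data = proc, cvs = cvs,
                 excluded = sel$excluded,
                 edge_seconds = 1 / params$band[1],
                 steps = c("linear_detrend", "tddr", "bandpass"),
                 params = params),
            class = "nirs_series")
}

#' Baseline-referenced block activation
#'
#' For each block, the mean signal over the task phase (onset to block end)
#' minus the mean over the `baseline_window` seconds immediately preceding
#' the onset. Blocks without enough pre-onset data are skipped with a
#' warning.
#'
#' @param x numeric vector (one channel).
#' @param events data.frame with `onset`, `duration`, `condition` (seconds,
#'   same clock as the series).
#' @param rate sampling rate, Hz.
#' @param baseline_window baseline length, seconds.
#' @param t0 time of the first sample, seconds.
#' @return data.frame: `block`, `condition`, `activation`.
#' @export
block_activation <- function(x, events, rate, baseline_window = 5, t0 = 0) {
  t <- t0 + (seq_along(x) - 1) / rate
  res <- lapply(seq_len(nrow(events)), function(b) {
    on <- events$onset[b]; off <- on + events$duration[b]
    if (on - baseline_window < t[1]) {
      warning(sprintf("block %d skipped: needs %gs of pre-onset baseline",
                      b, baseline_window))
      return(NULL)
    }
    task <- x[t >= on & t < off]
    base <- x[t >= on - baseline_window & t < on]
    data.frame(block = b, condition = events$condition[b],
               activation = mean(task) - mean(base))
  })
  do.call(rbind, res)
}

#' Block activations for every retained channel of a recording
#'
#' @param series a (typically preprocessed) `nirs_series`.
#' @param events the subject's block schedule/events table.
#' @param baseline_window baseline length, seconds.
#' @return data.frame: `subject`, `block`, `condition`, `channel`,
#'   `activation`.
#' @export
series_block_activation <- function(series, events, baseline_window = 5) {
  res <- lapply(colnames(series$data), function(ch) {
    ba <- block_activation(series$data[, ch], events, series$rate,
                           baseline_window, t0 = series$time[1])
    if (is.null(ba)) return(NULL)
    ba$channel <- ch
    ba
  })
  out <- do.call(rbind, res)
  out$subject <- series$subject
  out[, c("subject", "block", "condition", "channel", "activation")]
}
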