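# Canonical-HRF GLM activation estimates and probability-weighted ROI betas.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (shapes 6 and 16, unit dispersions,
#' peak-to-undershoot ratio 6:1), the standard impulse response linking a
#' neural event to the oxy-Hb response. The amplitude is normalized so the
#' peak equals 1.
#'
#' @param t time since the event, seconds (>= 0; vectorised).
#' @return HRF amplitude at `t`.
#' @export
canonical_hrf <- function(t) {
  raw <- function(u) stats::dgamma(u, 6, 1) - stats::dgamma(u, 16, 1) / 6
  peak <- max(raw(seq(0, 30, by = 0.001)))
  ifelse(t < 0, 0, raw(t) / peak)
}

#' Build the block-design GLM design matrix
#'
#' One regressor per condition: a unit boxcar over that condition's blocks
#' convolved with [canonical_hrf()] on the sampling grid, truncated to the
#' series length and peak-normalized to 1, plus an intercept column.
#'
#' @param events data.frame with `onset`, `duration`, `condition` (seconds).
#' @param n number of samples in the series.
#' @param rate sampling rate, Hz.
#' @param conditions condition order for the columns; defaults to order of
#'   first appearance.
#' @return list: `matrix` (n x (k+1), intercept first), `conditions`,
#'   `condition_cols` (column indices of the condition regressors), `rate`.
#' @export
build_design <- function(events, n, rate, conditions = unique(events$condition)) {
  ev <- events[order(events$onset), ]
  if (nrow(ev) > 1 &&
      any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)] - 1e-9))
    stop_domain("build_design: overlapping blocks in events")
  if (max(ev$onset) > n / rate)
    stop_domain("build_design: events extend beyond the series")
  kern <- canonical_hrf(seq(0, 32, by = 1 / rate))
  tgrid <- (seq_len(n) - 1) / rate
  cols <- vapply(conditions, function(cc) {
    box <- rep(0, n)
    for (b in which(ev$condition == cc))
      box[tgrid >= ev$onset[b] & tgrid < ev$onset[b] + ev$duration[b]] <- 1
    reg <- stats::convolve(box, rev(kern), type = "open")[seq_len(n)]
    if (max(abs(reg)) > 0) reg <- reg / max(reg)
    reg
  }, numeric(n))
  X <- cbind(intercept = 1, cols)
  colnames(X) <- c("intercept", conditions)
  list(matrix = X, conditions = conditions,
       condition_cols = seq_along(conditions) + 1L, rate = rate)
}

#' Fit the channel GLM by ordinary least squares
#'
#' @param y preprocessed channel series.
#' @param design a design from [build_design()].
#' @return list: `betas` (named per condition), `intercept`, `sigma`
#'   (residual SD), `residuals`, `fitted`.
#' @export
fit_glm <- function(y, design) {
  X <- design$matrix
  if (length(y) != nrow(X))
    stop_domain("fit_glm: series length %d != design rows %d",
                length(y), nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_domain("fit_glm: design is rank deficient (collinear: %s)",
                paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  fitted <- as.numeric(X %*% coef)
  res <- y - fitted
  list(betas = coef[design$conditions], intercept = coef[["intercept"]],
       sigma = sqrt(sum(res^2) / (length(y) - ncol(X))),
       residuals = res, fitted = fitted)
}

#' Channel-wise activation betas for a recording
#'
#' Builds the subject's design from the block schedule and fits the OLS GLM
#' to every retained channel. When the series carries preprocessing
#' parameters (it came through [preprocess_series()]), the condition
#' regressors are passed through the same linear detrending and zero-phase
#' band-pass as the data, so the temporal filtering cancels out of the
#' betas instead of attenuating them condition-differentially.
#'
#' @param series preprocessed `nirs_series`.
#' @param events the subject's schedule/events table.
#' @param conditions condition column order (defaults to appearance order).
#' @return data.frame: `subject`, `channel`, `condition`, `beta`.
#' @export
fit_channel_betas <- function(series, events,
                              conditions = unique(events$condition)) {
  design <- build_design(events, nrow(series$data), series$rate, conditions)
  if (!is.null(series$params)) {
    p <- series$params
    for (j in design$condition_cols)
      design$matrix[, j] <- bandpass(linear_detrend(design$matrix[, j]),
                                     series$rate, p$band, p$filter_order)
  }
  res <- lapply(colnames(series$data), function(ch) {
    fit <- fit_glm(series$data[, ch], design)
    data.frame(subject = series$subject, channel = ch,
               condition = names(fit$betas), beta = as.numeric(fit$betas),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Probability-weighted ROI activation
#'
#' Aggregates channel betas into a region-of-interest value using the
#' probabilistic registration: the `top_k` channels of the ROI with the
#' highest registration probability (ties broken towards the lower channel
#' id) contribute `sum(P_i * beta_i) / sum(P_i)`. The result is a convex
#' combination of the contributing betas. If fewer than `top_k` registered
#' channels were retained, all available ones are used with a warning.
#'
#' @param betas data.frame from [fit_channel_betas()] (one subject).
#' @param registration registration table ([generate_registration()]).
#' @param roi one of `"contra_BA4"`, `"contra_BA6"`, `"ipsi_BA4"`,
#'   `"ipsi_BA6"`; contralateral = left hemisphere (right-hand task).
#' @param top_k number of channels to aggregate.
#' @return data.frame: `subject`, `roi`, `condition`, `beta`.
#' @export
roi_beta <- function(betas, registration, roi, top_k = 3) {
  parts <- strsplit(roi, "_BA")[[1]]
  hemi <- if (parts[1] == "contra") "L" else "R"
  ba <- as.integer(parts[2])
  cand <- registration[registration$hemisphere == hemi &
                         registration$ba_label == ba, ]
  cand$channel_id <- sprintf("ch%02d", cand$channel)
  cand <- cand[cand$channel_id %in% unique(betas$channel), ]
  cand <- cand[order(-cand$probability, cand$channel), ]
  if (nrow(cand) == 0)
    stop_domain("roi_beta: no retained channels registered to %s", roi)
  if (nrow(cand) < top_k)
    warning(sprintf("roi_beta: only %d retained channel(s) in %s (top_k=%d)",
                    nrow(cand), roi, top_k))
  top <- utils::head(cand, top_k)
  sub <- betas[betas$channel %in% top$channel_id, ]
  res <- lapply(split(sub, sub$condition), function(d) {
    P <- top$probability[match(d$channel, top$channel_id)]
    data.frame(subject = d$subject[1], roi = roi, condition = d$condition[1],
               beta = sum(P * d$beta) / sum(P), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' ROI betas for all four motor ROIs
#'
#' @inheritParams roi_beta
#' @param rois ROI labels to aggregate.
#' @return stacked data.frame from [roi_beta()].
#' @export
all_roi_betas <- function(betas, registration,
                          rois = names(roi_channels()), top_k = 3) {
  do.call(rbind, lapply(rois, function(r)
    roi_beta(betas, registration, r, top_k)))
}
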