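# Conditional R-squared, univariate tests and marginal-means contrasts.

#' Conditional R-squared of a mixed fit
#'
#' Proportion of total response variance explained jointly by fixed and
#' random effects: `(var_f + sigma2_subject) / (var_f + sigma2_subject +
#' sigma2_resid)`, where `var_f` is the variance of the fixed-effect
#' predictions. For the logistic family the residual variance is the
#' standard-logistic variance `pi^2 / 3` on the latent scale.
#'
#' @param fit a `mixed_fit` from [fit_lmm()] or [fit_glmm_logistic()].
#' @return value in `[0, 1]`.
#' @export
conditional_r2 <- function(fit) {
  var_f <- stats::var(fit$fitted_fixed)
  resid_var <- if (fit$family == "gaussian") fit$sigma2_resid else pi^2 / 3
  num <- var_f + fit$sigma2_subject
  if (num + resid_var == 0) return(0)
  num / (num + resid_var)
}

#' One-sample t-tests with Bonferroni correction
#'
#' Two-sided t-test of `values` against zero, with the p-value multiplied by
#' the number of comparisons in the family (clamped at 1). Used channel-wise
#' on per-block activations.
#'
#' @param values numeric vector (n >= 2).
#' @param m family size for the Bonferroni adjustment.
#' @return data.frame: `statistic`, `df`, `p`, `p_adj`, `method`; `p` is NA
#'   (flagged) when the values have zero variance.
#' @export
one_sample_t_bonferroni <- function(values, m = 1) {
  if (length(values) < 2)
    stop_domain("one_sample_t_bonferroni: need n >= 2")
  if (stats::sd(values) == 0) {
    return(data.frame(statistic = NA_real_, df = length(values) - 1,
                      p = NA_real_, p_adj = NA_real_,
                      method = "one-sample t (zero variance)"))
  }
  tt <- stats::t.test(values, mu = 0)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, p_adj = min(1, m * tt$p.value),
             method = "one-sample t, Bonferroni")
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Statistic `W` is the sum of the ranks of the positive values (zeros
#' dropped); with 16 strictly positive values `W = 16 * 17 / 2 = 136`. The
#' p-value is exact for n <= 25 and a normal approximation beyond.
#'
#' @param values numeric vector (n >= 5 after dropping zeros).
#' @return data.frame: `statistic`, `n`, `p`, `method`.
#' @export
wilcoxon_one_sample <- function(values) {
  values <- values[values != 0]
  n <- length(values)
  if (n < 5) stop_domain("wilcoxon_one_sample: need n >= 5 nonzero values")
  wt <- stats::wilcox.test(values, mu = 0, exact = n <= 25)
  data.frame(statistic = unname(wt$statistic), n = n, p = wt$p.value,
             method = "Wilcoxon signed-rank")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Companion to [wilcoxon_one_sample()] for comparing two independent
#' samples (the one-sample signed-rank form is what a maximal statistic of
#' `n(n+1)/2` over n paired values corresponds to, and is what the default
#' reports use for ROI-against-zero activation).
#'
#' @param x,y numeric samples.
#' @return data.frame: `statistic`, `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  wt <- stats::wilcox.test(x, y)
  data.frame(statistic = unname(wt$statistic), p = wt$p.value,
             method = "Wilcoxon rank-sum")
}

#' Pairwise condition contrasts from a factorial mixed fit
#'
#' Model-predicted cell means on the linear predictor at every distance x
#' width cell (random effect at zero), with Wald tests of all pairwise
#' differences, Bonferroni-adjusted over the number of pairs.
#'
#' @param fit a `mixed_fit` whose fixed part contains `D`, `W` and their
#'   interaction.
#' @param grid optional data.frame of cells (`D`, `W`); defaults to the
#'   cells observed in the fitted data.
#' @return list: `cells` (cell means and SEs), `contrasts` (estimate, SE, z,
#'   raw and adjusted p per pair).
#' @export
emm_pairwise <- function(fit, grid = NULL) {
  tl <- attr(fit$terms, "term.labels")
  if (!all(c("D", "W") %in% tl) || !any(grepl(":", tl)))
    stop_domain("emm_pairwise: fit must contain D, W and their interaction")
  if (is.null(grid)) {
    mf <- fit$model_frame
    grid <- unique(data.frame(D = mf$D, W = mf$W))
    grid <- grid[order(grid$D, grid$W), , drop = FALSE]
  }
  L <- stats::model.matrix(stats::delete.response(fit$terms), grid)
  est <- as.numeric(L %*% fit$beta)
  se <- sqrt(diag(L %*% fit$vcov_beta %*% t(L)))
  cells <- data.frame(condition = sprintf("D%gW%g", grid$D, grid$W),
                      D = grid$D, W = grid$W, emm = est, se = se)
  pairs <- utils::combn(nrow(grid), 2)
  m <- ncol(pairs)
  ctr <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- L[i, ] - L[j, ]
    dest <- sum(d * fit$beta)
    dv <- drop(t(d) %*% fit$vcov_beta %*% d)
    dse <- if (is.finite(dv) && dv > 0) sqrt(dv) else NA_real_
    z <- dest / dse
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(contrast = paste(cells$condition[i], "-", cells$condition[j]),
               estimate = dest, se = dse, statistic = z, p = p,
               p_adj = min(1, m * p))
  })
  list(cells = cells, contrasts = do.call(rbind, ctr))
}

#' Fit the study's full set of mixed models
#'
#' Fits the eight reported random-intercept models: success ~ D*W and
#' success ~ ID (logistic); MT ~ ID and MT ~ D*W (linear, successful trials
#' only); and, per contralateral ROI, beta ~ ID and beta ~ D*W (linear).
#' Returns the fits plus a tidy results table with conditional R-squared per
#' model.
#'
#' @param trials pooled trial table from [simulate_trials()].
#' @param roi_betas pooled ROI beta table from [all_roi_betas()], annotated
#'   with `D`, `W`, `ID` (see [annotate_conditions()]).
#' @param rois ROI labels to model.
#' @param agq Gauss-Hermite nodes for the logistic fits (1 = Laplace).
#' @return list: `fits` (named list of `mixed_fit`), `table` (data.frame
#'   with model, term, estimate, se, statistic, df, p, cond_r2).
#' @export
run_paper_models <- function(trials, roi_betas,
                             rois = c("contra_BA4", "contra_BA6"),
                             agq = 1) {
  succ <- trials[trials$success, ]
  fits <- list(
    success_dw = fit_glmm_logistic(success ~ D * W + (1 | subject), trials,
                                   agq = agq),
    success_id = fit_glmm_logistic(success ~ ID + (1 | subject), trials,
                                   agq = agq),
    mt_id = fit_lmm(MT ~ ID + (1 | subject), succ),
    mt_dw = fit_lmm(MT ~ D * W + (1 | subject), succ))
  for (r in rois) {
    rb <- roi_betas[roi_betas$roi == r, ]
    fits[[paste0("beta_id_", r)]] <- fit_lmm(beta ~ ID + (1 | subject), rb)
    fits[[paste0("beta_dw_", r)]] <- fit_lmm(beta ~ D * W + (1 | subject), rb)
  }
  table <- do.call(rbind, lapply(names(fits), function(nm) {
    ct <- fits[[nm]]$coefficients
    ct$model <- nm
    ct$cond_r2 <- conditional_r2(fits[[nm]])
    ct[, c("model", "term", "estimate", "se", "statistic", "df", "p",
           "cond_r2")]
  }))
  list(fits = fits, table = table)
}

#' Annotate a condition-labelled table with D, W and ID
#'
#' @param x data.frame with a `condition` column.
#' @param conditions condition table (default [default_conditions()]).
#' @return `x` with `D`, `W`, `ID` columns merged in.
#' @export
annotate_conditions <- function(x, conditions = default_conditions()) {
  i <- match(x$condition, conditions$condition)
  if (anyNA(i)) stop_domain("annotate_conditions: unknown condition label")
  x$D <- conditions$D[i]; x$W <- conditions$W[i]; x$ID <- conditions$ID[i]
  x
}
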