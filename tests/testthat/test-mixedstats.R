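lme4_ok <- requireNamespace("lme4", quietly = TRUE) &&
  requireNamespace("lmerTest", quietly = TRUE)

test_that("the REML LMM matches the reference mixed-model fit on a fixture", {
  skip_if_not(lme4_ok, "lme4/lmerTest not available")
  d <- make_lmm_data(99)
  f <- fit_lmm(MT ~ ID + (1 | subject), d)
  m <- lmerTest::lmer(MT ~ ID + (1 | subject), d)
  cs <- coef(summary(m))
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-4)
  expect_equal(f$coefficients$se, unname(cs[, "Std. Error"]),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$sigma2_subject, vc$vcov[1], tolerance = 1e-4)
  expect_equal(f$sigma2_resid, vc$vcov[2], tolerance = 1e-4)
  # Satterthwaite degrees of freedom and p-values agree with lmerTest
  expect_equal(f$coefficients$df, unname(cs[, "df"]), tolerance = 1e-2)
  expect_equal(f$coefficients$p, unname(cs[, "Pr(>|t|)"]), tolerance = 1e-4)
  expect_true(all(f$coefficients$df <= f$n - 2))
})

test_that("a boundary (singular) LMM fit reduces to ordinary least squares", {
  # pick a null-variance dataset whose REML estimate lands on the boundary
  found <- FALSE
  for (seed in 1:20) {
    d <- make_lmm_data(seed, sd_subj = 0)
    f <- fit_lmm(MT ~ ID + (1 | subject), d)
    if (f$singular) {
      ols <- stats::lm(MT ~ ID, d)
      expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-6)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("the LMM recovers a known Fitts slope over replicates", {
  slopes <- vapply(1:50, function(r) {
    d <- make_lmm_data(3000 + r, J = 16, nper = 60, slope = 0.2974)
    fit_lmm(MT ~ ID + (1 | subject), d)$beta[["ID"]]
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.2974), 2 * mc_se)
})

test_that("LMM slope test keeps its nominal type-I error under the null", {
  rej <- vapply(1:1000, function(r) {
    d <- make_lmm_data(50000 + r, J = 16, nper = 20, slope = 0)
    fit_lmm(MT ~ ID + (1 | subject), d)$coefficients$p[2] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("the Laplace GLMM matches the reference fit and its degeneracies", {
  skip_if_not(lme4_ok, "lme4 not available")
  d <- make_glmm_data(11)
  f <- fit_glmm_logistic(success ~ ID + (1 | subject), d)
  m <- suppressMessages(suppressWarnings(
    lme4::glmer(success ~ ID + (1 | subject), d, family = stats::binomial())))
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(unname(sqrt(f$sigma2_subject)),
               unname(sqrt(unlist(lme4::VarCorr(m)))[1]), tolerance = 1e-2)
  expect_equal(f$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-3)
  # sigma_b = 0 generating process: a boundary fit matches plain logistic ML
  for (seed in 12:31) {
    d0 <- make_glmm_data(seed, sd_subj = 0)
    f0 <- fit_glmm_logistic(success ~ ID + (1 | subject), d0)
    if (f0$singular) break
  }
  expect_true(f0$singular)
  g0 <- stats::glm(success ~ ID, stats::binomial(), d0)
  expect_equal(unname(f0$beta), unname(coef(g0)), tolerance = 1e-3)
})

test_that("the GLMM recovers a known difficulty coefficient over replicates", {
  ests <- vapply(1:30, function(r) {
    d <- make_glmm_data(7000 + r, J = 16, nper = 60)
    fit_glmm_logistic(success ~ ID + (1 | subject), d)$beta[["ID"]]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-1.3407)), 2 * mc_se)
})

test_that("adaptive Gauss-Hermite refinement agrees with Laplace at scale", {
  d <- make_glmm_data(21, J = 8, nper = 60)
  f1 <- fit_glmm_logistic(success ~ ID + (1 | subject), d, agq = 1)
  f9 <- fit_glmm_logistic(success ~ ID + (1 | subject), d, agq = 9)
  expect_equal(unname(f1$beta), unname(f9$beta), tolerance = 5e-2)
  expect_gte(f9$logLik, f1$logLik - 0.5)
})

test_that("conditional R-squared follows its variance decomposition", {
  d <- make_lmm_data(31)
  f <- fit_lmm(MT ~ ID + (1 | subject), d)
  r2 <- conditional_r2(f)
  expect_true(r2 >= 0 && r2 <= 1)
  if (lme4_ok) {
    m <- lme4::lmer(MT ~ ID + (1 | subject), d)
    vc <- as.data.frame(lme4::VarCorr(m))
    vf <- stats::var(as.numeric(stats::model.matrix(m) %*% lme4::fixef(m)))
    ref <- (vf + vc$vcov[1]) / (vf + vc$vcov[1] + vc$vcov[2])
    expect_equal(r2, ref, tolerance = 1e-4)
  }
  # noiseless fit explains everything
  d2 <- make_lmm_data(32, sd_res = 1e-6)
  expect_gte(conditional_r2(fit_lmm(MT ~ ID + (1 | subject), d2)), 0.999)
  # no fixed effects, no random variance: nothing explained
  d3 <- make_lmm_data(33, slope = 0, sd_subj = 0)
  d3$MT <- stats::rnorm(nrow(d3))
  f3 <- fit_lmm(MT ~ 1 + (1 | subject), d3)
  f3$beta[] <- 0
  f3$fitted_fixed[] <- 0
  f3$sigma2_subject <- 0
  expect_equal(conditional_r2(f3), 0)
})

test_that("conditional R2 grows as generator noise shrinks", {
  mean_r2 <- vapply(c(0.3, 0.15, 0.05), function(s) {
    mean(vapply(1:20, function(r) {
      d <- make_lmm_data(9000 + r, J = 8, nper = 30, sd_res = s)
      conditional_r2(fit_lmm(MT ~ ID + (1 | subject), d))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) > 0))
})

test_that("one-sample t tests with Bonferroni behave as textbook", {
  sym <- c(-1, 1, -1, 1, -2, 2)
  res <- one_sample_t_bonferroni(sym, m = 4)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$p_adj, 1)           # m * p clamped at 1
  # hand computation on a 5-value fixture
  v <- c(0.2, 0.5, 0.1, 0.4, 0.3)
  tt <- mean(v) / (sd(v) / sqrt(5))
  res2 <- one_sample_t_bonferroni(v, m = 44)
  expect_equal(res2$statistic, tt, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(tt), 4), tolerance = 1e-12)
  expect_equal(res2$p_adj, min(1, 44 * res2$p))
  # zero variance is flagged, not an error
  expect_true(is.na(one_sample_t_bonferroni(rep(1, 5))$p))
})

test_that("the signed-rank statistic and exact p match enumeration", {
  # 16 strictly positive values: W is the maximal rank sum 16*17/2
  pos <- abs(rnorm(16)) + 0.1
  res <- wilcoxon_one_sample(pos)
  expect_equal(unname(res$statistic), 136)
  expect_lt(res$p, 0.001)
  # exact p for n = 6 all positive: 2 / 2^6
  res6 <- wilcoxon_one_sample(c(1, 2, 3, 4, 5, 6) / 10)
  expect_equal(res6$p, 0.03125)
  # enumeration oracle over all sign patterns for n = 8
  set.seed(5)
  x <- round(rnorm(8, 0.3), 3)
  x <- x[x != 0]
  n <- length(x)
  W_obs <- sum(rank(abs(x))[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- signs %*% rank(abs(x))
  p_enum <- mean(pmin(1, 2 * pmin(mean(Wnull >= W_obs), mean(Wnull <= W_obs))))
  expect_equal(res_p <- wilcoxon_one_sample(x)$p, p_enum, tolerance = 1e-10)
  # zeros are dropped
  expect_equal(unname(wilcoxon_one_sample(c(0, 1, 2, 3, 4, 5, 0.5))$statistic),
               21)
  expect_error(wilcoxon_one_sample(c(0, 0, 1, 2)), "n >= 5")
})

test_that("the rank-sum companion test wraps the two-sample statistic", {
  set.seed(6)
  x <- rnorm(10); y <- rnorm(12) + 2
  res <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y)
  expect_equal(unname(res$statistic), unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("pairwise condition contrasts equal brute-force cell differences", {
  cfg <- sim_config(n_subjects = 12, master_seed = 61)
  tr <- do.call(rbind, lapply(1:12, function(s)
    simulate_trials(generate_schedule(cfg, s), cfg)))
  fit <- fit_glmm_logistic(success ~ D * W + (1 | subject), tr)
  pw <- emm_pairwise(fit)
  expect_equal(nrow(pw$contrasts), 6)
  expect_true(all(pw$contrasts$p_adj >= pw$contrasts$p - 1e-15))
  # cell means by direct prediction
  cells <- pw$cells
  for (k in seq_len(nrow(cells))) {
    eta <- fit$beta[["(Intercept)"]] + fit$beta[["D"]] * cells$D[k] +
      fit$beta[["W"]] * cells$W[k] + fit$beta[["D:W"]] * cells$D[k] * cells$W[k]
    expect_equal(cells$emm[k], unname(eta), tolerance = 1e-10)
  }
  for (k in seq_len(nrow(pw$contrasts))) {
    nm <- strsplit(pw$contrasts$contrast[k], " - ")[[1]]
    diff_brute <- cells$emm[match(nm[1], cells$condition)] -
      cells$emm[match(nm[2], cells$condition)]
    expect_equal(pw$contrasts$estimate[k], diff_brute, tolerance = 1e-10)
  }
  expect_error(emm_pairwise(fit_glmm_logistic(success ~ ID + (1 | subject),
                                              tr)),
               "interaction")
})

test_that("pairwise contrasts match the marginal-means oracle", {
  skip_if_not(lme4_ok && requireNamespace("emmeans", quietly = TRUE),
              "lme4/emmeans not available")
  d <- make_lmm_data(71)
  d$D <- sample(c(200, 600), nrow(d), TRUE)
  d$W <- sample(c(40, 120), nrow(d), TRUE)
  d$MT <- 0.5 + 1e-3 * d$D - 2e-3 * d$W + rnorm(nrow(d), 0, 0.1) +
    rnorm(16, 0, 0.05)[d$subject]
  f <- fit_lmm(MT ~ D * W + (1 | subject), d)
  pw <- emm_pairwise(f)
  m <- suppressWarnings(lme4::lmer(MT ~ D * W + (1 | subject), d))
  em <- as.data.frame(emmeans::emmeans(m, ~ D * W,
                                       at = list(D = c(200, 600),
                                                 W = c(40, 120))))
  em$condition <- sprintf("D%gW%g", em$D, em$W)
  expect_equal(pw$cells$emm[match(em$condition, pw$cells$condition)],
               em$emmean, tolerance = 1e-3)
})

test_that("a D-only-at-small-W effect is detected where it exists", {
  hits_small <- 0; hits_big <- 0; nrep <- 20
  for (r in seq_len(nrep)) {
    set.seed(40000 + r)
    J <- 16; nper <- 120
    d <- data.frame(subject = rep(1:J, each = nper),
                    D = sample(c(200, 600), J * nper, TRUE),
                    W = sample(c(40, 120), J * nper, TRUE))
    # strong D effect only at W = 40
    eta <- 2.5 - 2.2 * (d$D == 600 & d$W == 40) + rnorm(J, 0, 0.3)[d$subject]
    d$success <- runif(nrow(d)) < plogis(eta)
    fit <- fit_glmm_logistic(success ~ D * W + (1 | subject), d)
    pw <- emm_pairwise(fit)$contrasts
    p_small <- pw$p_adj[pw$contrast == "D200W40 - D600W40"]
    p_big <- pw$p_adj[pw$contrast == "D200W120 - D600W120"]
    if (p_small < 0.05) hits_small <- hits_small + 1
    if (p_big >= 0.05) hits_big <- hits_big + 1
  }
  expect_gte(hits_small / nrep, 0.9)
  expect_gte(hits_big / nrep, 0.9)
})

test_that("the full model report covers all eight study models", {
  cfg <- sim_config(n_subjects = 8, master_seed = 81)
  tr <- do.call(rbind, lapply(1:8, function(s)
    simulate_trials(generate_schedule(cfg, s), cfg)))
  # synthetic ROI betas with a known positive structure
  set.seed(81)
  rb <- expand.grid(subject = 1:8, roi = c("contra_BA4", "contra_BA6"),
                    condition = cfg$conditions$condition,
                    stringsAsFactors = FALSE)
  rb <- annotate_conditions(rb, cfg$conditions)
  rb$beta <- 0.02 + 1e-5 * rb$D + rnorm(nrow(rb), 0, 0.005)
  rep <- run_paper_models(tr, rb)
  expect_length(rep$fits, 8)
  expect_setequal(unique(rep$table$model),
                  c("success_dw", "success_id", "mt_id", "mt_dw",
                    "beta_id_contra_BA4", "beta_dw_contra_BA4",
                    "beta_id_contra_BA6", "beta_dw_contra_BA6"))
  expect_true(all(c("estimate", "se", "p", "cond_r2") %in% names(rep$table)))
  expect_true(all(rep$table$cond_r2 >= 0 & rep$table$cond_r2 <= 1))
  # the MT ~ ID slope is positive and significant by construction
  mt <- rep$table[rep$table$model == "mt_id" & rep$table$term == "ID", ]
  expect_gt(mt$estimate, 0)
  expect_lt(mt$p, 0.001)
})

test_that("mixed-model formulas are validated", {
  d <- make_lmm_data(1)
  expect_error(fit_lmm(MT ~ ID, d), "random term")
  expect_error(fit_lmm(MT ~ ID + (ID | subject), d), "random intercepts")
  expect_error(fit_glmm_logistic(MT ~ ID + (1 | subject), d), "binary")
})
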