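#!/usr/bin/env Rscript
# Inferential stage: the eight random-intercept mixed models (success ~ D*W
# and ~ ID logistic; MT ~ ID and ~ D*W linear; ROI beta ~ ID and ~ D*W per
# contralateral ROI), channel-wise one-sample t-tests with Bonferroni
# correction, signed-rank ROI activation tests, and pairwise condition
# contrasts on success probability. Writes results/model_table.csv,
# results/channel_tests.csv, results/roi_tests.csv, results/results.json.

suppressMessages(library(fittsnirs))

trials <- read_trials("results/data/trials.csv")
rois <- read.csv("results/roi_betas.csv")
acts <- read.csv("results/block_activations.csv")

models <- run_paper_models(trials, rois)
write.csv(models$table, "results/model_table.csv", row.names = FALSE)

# channel-wise activation vs 0, Bonferroni within condition over channels
ch_tests <- do.call(rbind, lapply(
  split(acts, list(acts$condition, acts$channel)), function(d) {
    res <- one_sample_t_bonferroni(d$activation,
                                   m = length(unique(acts$channel)))
    cbind(condition = d$condition[1], channel = d$channel[1], res)
  }))
write.csv(ch_tests, "results/channel_tests.csv", row.names = FALSE)

# ROI-wise signed-rank activation vs 0 (per-subject mean betas)
roi_tests <- do.call(rbind, lapply(split(rois, rois$roi), function(d) {
  res <- wilcoxon_one_sample(as.numeric(tapply(d$beta, d$subject, mean)))
  cbind(roi = d$roi[1], res)
}))
write.csv(roi_tests, "results/roi_tests.csv", row.names = FALSE)

pw <- emm_pairwise(models$fits$success_dw)
write.csv(pw$contrasts, "results/success_pairwise.csv", row.names = FALSE)

write_results_json(list(
  mt_id_slope = models$fits$mt_id$beta[["ID"]],
  mt_id_cond_r2 = conditional_r2(models$fits$mt_id),
  success_id_coef = models$fits$success_id$beta[["ID"]],
  success_id_cond_r2 = conditional_r2(models$fits$success_id),
  roi_wilcoxon = roi_tests[, c("roi", "statistic", "p")],
  n_significant_channel_tests = sum(ch_tests$p_adj < 0.05, na.rm = TRUE)
), "results/results.json")

mt <- models$fits$mt_id$coefficients
message(sprintf("MT ~ ID: slope %.4f s/bit (SE %.4f, p %.2g), conditional R2 %.3f",
                mt$estimate[2], mt$se[2], mt$p[2],
                conditional_r2(models$fits$mt_id)))
sc <- models$fits$success_id$coefficients
message(sprintf("success ~ ID: %.4f per bit (p %.2g), conditional R2 %.3f",
                sc$estimate[2], sc$p[2],
                conditional_r2(models$fits$success_id)))
message(sprintf("ROI signed-rank statistics: %s",
                paste(sprintf("%s W=%g", roi_tests$roi, roi_tests$statistic),
                      collapse = ", ")))
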