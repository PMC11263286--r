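#!/usr/bin/env Rscript
# Hemodynamic processing chain: linear detrend -> TDDR -> 0.01-0.08 Hz
# zero-phase Butterworth band-pass, channel CV screening, baseline-
# referenced block activations, channel GLM betas, and probability-weighted
# ROI betas. Reads results/data/, writes results/*.csv.

suppressMessages(library(fittsnirs))

registration <- read_registration("results/data/registration.csv")
params <- preprocess_params()

betas <- list(); rois <- list(); acts <- list(); n_excluded <- 0
subjects <- seq_along(list.files("results/data", "^series_sub"))
for (s in subjects) {
  events <- read_events(sprintf("results/data/events_sub%02d.tsv", s))
  raw <- read_series(sprintf("results/data/series_sub%02d.csv", s),
                     subject = s)
  proc <- preprocess_series(raw, params)
  n_excluded <- n_excluded + length(proc$excluded)
  betas[[s]] <- fit_channel_betas(proc, events)
  rois[[s]] <- all_roi_betas(betas[[s]], registration)
  acts[[s]] <- series_block_activation(proc, events, params$baseline_window)
}
betas <- do.call(rbind, betas)
rois <- annotate_conditions(do.call(rbind, rois))
acts <- do.call(rbind, acts)

write.csv(betas, "results/channel_betas.csv", row.names = FALSE)
write.csv(rois, "results/roi_betas.csv", row.names = FALSE)
write.csv(acts, "results/block_activations.csv", row.names = FALSE)

message(sprintf("Excluded %d of %d channel recordings (%.2f%%) by the CV > %g%% rule",
                n_excluded, length(subjects) * 44,
                100 * n_excluded / (length(subjects) * 44), params$cv_threshold))
message(sprintf("Mean contralateral ROI beta: BA4 %.4f, BA6 %.4f",
                mean(rois$beta[rois$roi == "contra_BA4"]),
                mean(rois$beta[rois$roi == "contra_BA6"])))
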