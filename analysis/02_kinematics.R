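#!/usr/bin/env Rscript
# Kinematic analysis of the simulated study: per-condition movement time,
# success and overshoot rates, and throughput; per-subject throughput for
# the grand mean. Reads results/data/, writes results/kinematics_*.csv.

suppressMessages(library(fittsnirs))

trials <- read_trials("results/data/trials.csv")

summ <- kinematic_summary(trials)
write.csv(summ, "results/kinematics_by_condition.csv", row.names = FALSE)

tp <- do.call(rbind, lapply(split(trials, trials$subject), function(d) {
  data.frame(subject = d$subject[1], TP = throughput(d)$TP,
             success_pct = 100 * mean(d$success),
             overshoot_pct = overshoot_rate(d))
}))
write.csv(tp, "results/kinematics_by_subject.csv", row.names = FALSE)

message(sprintf("Grand mean throughput %.3f +/- %.3f bit/s over %d subjects",
                mean(tp$TP), sd(tp$TP), nrow(tp)))
message(sprintf("Overshoot %% by condition (difficulty-ordered): %s",
                paste(sprintf("%s %.1f", summ$condition[order(summ$ID)],
                              summ$overshoot_pct[order(summ$ID)]),
                      collapse = ", ")))
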