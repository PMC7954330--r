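#!/usr/bin/env Rscript
# Step 4 — antagonist experiments: paired control-vs-application cohorts.
#
# Each slice contributes two consecutive segments (control medium, then
# the drug condition) sharing its slice-level random effect; the
# synchronization scores are compared pairwise with the Shapiro-Wilk-gated
# protocol (paired t or exact signed-rank). The blocked conditions (MEC,
# d-tubocurarine) should collapse the score; the no-effect antagonists
# (atropine, MLA, DhbetaE) should not reach significance.

library(fieldsync)

seed <- 20240917
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(
  condition_pairs = list(
    c("synaptic_blockers", "atropine_10uM"),
    c("synaptic_blockers", "d_tubocurarine_50uM"),
    c("synaptic_blockers", "mla_100nM"),
    c("synaptic_blockers", "dhbe_10uM"),
    c("synaptic_blockers", "mec_50uM")),
  n_slices = 6, duration = 600, seed = seed, sampling_rate = 1000,
  sync_window_s = 300)

cat("running 5 paired experiments x 6 slices (this is the slow step)...\n")
rep <- run_experiment(cfg)
print(rep)
write_report_table(rep, "results/antagonist_comparisons.csv")
cat("wrote results/antagonist_comparisons.csv\n")
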