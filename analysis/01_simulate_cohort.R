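#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic cohort.
#
# Draws ground-truth units for WT / HET / KO in the pre, post-familiar and
# post-novel conditions, simulates inhomogeneous-Poisson spike trains over
# the familiarity block and the three tuning protocols, and writes each
# genotype x condition recording to disk in the Phy-style layout
# (spike_times / spike_clusters / cluster_group + trials.csv + LFP binary
# with JSON sidecar + ground-truth sidecar TSV).
#
# Output: scratch/cohort/<genotype>_<condition>/ (large, regenerable)
#         results/cohort_summary.tsv

library(v1tune)

seed <- 20260927L
out_dir <- "scratch/cohort"
cfg <- default_cohort_config(n_units = 30)

message("Simulating 3 genotypes x 3 conditions, ",
        cfg$n_units, " units each ...")
cohort <- simulate_cohort(cfg, seed = seed,
                          n_familiar = 200,
                          orientation_repeats = 12,
                          sf_repeats = 20,
                          contrast_repeats = 24,
                          with_lfp = TRUE,
                          n_channels = 16, layer4_channel = 6)
write_cohort(cohort, out_dir)

summary_rows <- do.call(rbind, lapply(cohort$recordings, function(rec) {
  data.frame(genotype = rec$genotype, condition = rec$condition,
             n_units = nrow(rec$units),
             n_trials = sum(vapply(rec$protocols, nrow, numeric(1))),
             mean_true_osc_duration_s = mean(rec$units$osc_duration *
                                             rec$units$osc_enabled),
             mean_true_sigma_deg = mean(rec$units$sigma))
}))
rownames(summary_rows) <- NULL
dir.create("results", showWarnings = FALSE)
write.table(summary_rows, "results/cohort_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(summary_rows, digits = 3)
message("After experience the KO draws carry longer oscillations and ",
        "broader tuning than WT; naive (pre) genotypes are matched.")
message("Wrote ", out_dir, " and results/cohort_summary.tsv")
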