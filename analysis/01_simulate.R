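#!/usr/bin/env Rscript
# Cohort simulation: checks that the synthetic study population reproduces
# the target pressure distribution (SBP 125 +/- 18.8 mmHg in 90-175,
# DBP 76 +/- 12.4 in 54-105) and writes the cohort tables.

suppressPackageStartupMessages(library(cufflessbp))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

seed <- 20260923L

cat("== Synthetic cohort characteristics (n = 2000, fast path) ==\n")
ch <- generate_cohort(cohort_params(n = 2000, seed = seed), signals = FALSE)
tr <- ch$truth
summ <- data.frame(
  variable = c("sbp_true", "dbp_true", "hr_bpm", "ptt_ms_true"),
  mean = sapply(tr[c("sbp_true", "dbp_true", "hr_bpm", "ptt_ms_true")], mean),
  sd = sapply(tr[c("sbp_true", "dbp_true", "hr_bpm", "ptt_ms_true")], sd),
  min = sapply(tr[c("sbp_true", "dbp_true", "hr_bpm", "ptt_ms_true")], min),
  max = sapply(tr[c("sbp_true", "dbp_true", "hr_bpm", "ptt_ms_true")], max))
print(summ, row.names = FALSE, digits = 4)
stopifnot(all(tr$sbp_true > tr$dbp_true))
cat(sprintf("SBP mean %.1f (target 125), sd %.2f (target 18.8)\n",
            mean(tr$sbp_true), sd(tr$sbp_true)))
cat(sprintf("DBP mean %.1f (target 76),  sd %.2f (target 12.4)\n",
            mean(tr$dbp_true), sd(tr$dbp_true)))
cat(sprintf("cuff-mean vs true SBP residual sd: %.2f mmHg (expect ~%.2f)\n",
            sd(ch$cuff$sbp_cuff - tr$sbp_true), 3 / sqrt(3)))
write.csv(summ, "results/tables/cohort_summary.csv", row.names = FALSE)
write.csv(cbind(tr, ch$cuff[-1])[1:50, ],
          "results/tables/cohort_truth_head.csv", row.names = FALSE)

# one fully synthesized example record, saved in the interchange CSV format
cat("\n== Example recording (4 s @ 250 Hz) ==\n")
sr <- synthesize_recording("example", morphology_params(), 4, 250, 64,
                           noise_sd_ppg = 0.02, noise_sd_ecg = 0.02)
write_recording(sr$recording, "results/tables/example_recording.csv")
write.csv(sr$beat_truth, "results/tables/example_beat_truth.csv",
          row.names = FALSE)
print(sr$recording)
cat(sprintf("beats: %d, true PTT %.0f ms\n", nrow(sr$beat_truth),
            sr$beat_truth$ptt_ms[1]))
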