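#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic pirouette cohorts.
#
# 15 subjects x 2 tasks (jazz, classic) x 2 landmarks (left knee LKNE,
# center of mass CoM), each trial a single turn of 101-250 frames at
# 100 Hz. Trials are written as plain CSV under results/trials/ so every
# later stage can start from files on disk.

library(pirodyn)

out_dir <- file.path("results", "trials")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

base_seed <- 1L
tasks <- c("jazz", "classic")
landmarks <- c("LKNE", "CoM")

for (ti in seq_along(tasks)) {
  for (li in seq_along(landmarks)) {
    # same per-combination seed scheme as run_full_analysis(), so the
    # staged workflow and the one-shot pipeline agree
    seed <- base_seed + 97L * li + 389L * ti
    cohort <- generate_pirouette_cohort(15, tasks[ti], landmarks[li],
                                        seed = seed)
    for (tr in cohort) write_trial_csv(tr, out_dir)
  }
}

cat("wrote", length(list.files(out_dir)), "trial files to", out_dir, "\n")
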