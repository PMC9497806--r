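#!/usr/bin/env Rscript
# Stage 2: build the group-level composite series.
#
# For each (task, landmark) combination: read the 15 trials written by
# 01_simulate.R, resample each to 300 samples, normalize each coordinate by
# its maximum absolute value, concatenate in a seeded shuffled order with
# every second trial time-reversed, then drop the lowest 10% of values per
# coordinate (quantile reduction). One CSV per combination is written to
# results/composites/ with the three reduced coordinate series.

library(pirodyn)

trial_dir <- file.path("results", "trials")
out_dir <- file.path("results", "composites")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- list.files(trial_dir, full.names = TRUE)
trials <- lapply(files, read_trial_csv)
key <- vapply(trials, function(tr) paste(tr$task, tr$landmark, sep = "_"),
              character(1))

for (k in unique(key)) {
  cohort <- trials[key == k]
  normed <- lapply(cohort, function(tr) {
    normalize_by_max(resample_to_fixed_length(tr, 300))
  })
  comps <- build_composite(normed, seed = 1)
  reduced <- lapply(comps, quantile_reduce, p_low = 0.1)
  lens <- vapply(reduced, function(s) length(s$values), integer(1))
  cat(sprintf("%s: composite %d -> reduced %s\n", k,
              length(comps$x$values), paste(lens, collapse = "/")))
  # pad to a rectangular table (coordinates can keep different counts)
  n <- max(lens)
  tab <- data.frame(lapply(reduced, function(s) {
    c(s$values, rep(NA_real_, n - length(s$values)))
  }))
  utils::write.csv(tab, file.path(out_dir, paste0(k, ".csv")),
                   row.names = FALSE)
}
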