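#!/usr/bin/env Rscript
# Stage 3: characterize each reduced composite coordinate series.
#
# For every (task, landmark, coordinate) series from 02_build_series.R:
# rescaled-range Hurst exponent (with persistence classification), a
# windowed-drift stationarity check, and an IAAFT-surrogate nonlinearity
# test (time-reversal asymmetry, 99 surrogates). Results go to
# results/characterization.csv.

library(pirodyn)

comp_dir <- file.path("results", "composites")
files <- list.files(comp_dir, full.names = TRUE)

rows <- list()
for (f in files) {
  combo <- sub("\\.csv$", "", basename(f))
  tab <- utils::read.csv(f)
  for (coord in names(tab)) {
    v <- tab[[coord]][!is.na(tab[[coord]])]
    hur <- hurst_rs(v)
    st <- stationarity_test(v, seed = 1)
    nl <- nonlinearity_test(v, n_surrogates = 99, seed = 1)
    rows[[length(rows) + 1]] <- data.frame(
      series = paste0(combo, "_", coord),
      n = length(v),
      H = round(hur$H, 3),
      classification = hur$classification,
      stationary = !st$nonstationary,
      nonlinear = nl$rejected,
      surrogate_rank = nl$rank
    )
    cat(sprintf("%s_%s: H=%.3f (%s)\n", combo, coord, hur$H,
                hur$classification))
  }
}

out <- do.call(rbind, rows)
utils::write.csv(out, file.path("results", "characterization.csv"),
                 row.names = FALSE)
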