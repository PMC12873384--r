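#!/usr/bin/env Rscript
# Generate the reference synthetic gelation experiment: a GdL-triggered
# 10 mg/ml run (SANS every 5 min on 0.002-0.5 A^-1, pH, ThT, emission
# spectra, FTIR) plus a methanol-triggered comparison series, and write
# them as the CSV + manifest layout the rest of the workflow consumes.
# Run from the repository root: Rscript analysis/01_simulate.R

library(silkgel)

out <- "results/sample-gdl"
sample <- simulate_sample(seed = 1, dir = out)
cat("GdL reference sample:", length(sample$sans$frames), "frames ->", out, "\n")

met <- simulate_methanol_series(seed = 1)
dirm <- "results/sample-methanol"
dir.create(dirm, recursive = TRUE, showWarnings = FALSE)
frames <- lapply(met$series$frames, function(f) {
  fn <- sprintf("frame_%04d.csv", round(f$time_min))
  write_curve(f, file.path(dirm, fn))
  list(path = fn, time_min = f$time_min)
})
yaml::write_yaml(list(sample_label = met$series$sample_label,
                      trigger = "methanol", trigger_percent = 15,
                      rsf_mg_ml = 10, frames = frames),
                 file.path(dirm, "manifest.yaml"))
utils::write.csv(met$truth, file.path(dirm, "truth_trajectory.csv"),
                 row.names = FALSE)
cat("methanol comparison sample:", length(met$series$frames), "frames ->",
    dirm, "\n")
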