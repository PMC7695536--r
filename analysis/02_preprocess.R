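#!/usr/bin/env Rscript
# Apply the cohort inclusion criteria (>= 8 sensors, >= 355 days online) and
# collapse every retained household's 5-minute stream into the daily 48-slot
# binary day matrix.

library(pirvae)

panel_dir <- "results/panels"
outdir <- "results/day_matrices"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

manifest <- read.csv(file.path(panel_dir, "manifest.csv"))
kept <- apply_inclusion(manifest, inclusion_criteria(min_sensors = 8L,
                                                     min_days_online = 355L))
cat("inclusion: kept", nrow(kept), "of", nrow(manifest), "households:",
    paste(kept$household_id, collapse = ", "), "\n")

for (hid in kept$household_id) {
  panel <- read_sensor_panel(
    file.path(panel_dir, paste0(hid, "_activations.csv")),
    file.path(panel_dir, paste0(hid, "_labels.csv")),
    household_id = hid
  )
  dm <- build_day_matrix(panel)
  write_day_matrix(dm, file.path(outdir, paste0(hid, "_days.csv")))
  cat(sprintf("%s: %d complete days, %.1f%% motion-positive slots\n",
              hid, nrow(dm$X), 100 * mean(dm$X)))
}
write.csv(kept, file.path(outdir, "included.csv"), row.names = FALSE)
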