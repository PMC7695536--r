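#!/usr/bin/env Rscript
# Simulate a small cohort of synthetic households and export their raw
# 5-minute PIR sensor streams. Four households share a working-professional
# base schedule (wake 7:00, away 9:30-16:30, sleep 22:30) with +/-2 slot
# jitter and no away window at weekends; one household gets 20 labelled
# absence-mode anomaly days; one household falls below the sensor-count
# inclusion criterion on purpose.

library(pirvae)

outdir <- "results/panels"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

base <- household_spec(
  n_sensors = 8L, wake_slot = 14L, depart_slot = 19L, return_slot = 33L,
  sleep_slot = 45L,
  weekend_profile = list(depart_slot = NA, return_slot = NA),
  p_fire_active = 0.25, p_fire_idle = 0.005,
  n_days = 365L, missing_day_rate = 0.01, seed = 1L
)

panels <- generate_cohort(4L, base, seed = 2024L, jitter_slots = 2L)

# household with ground-truth anomalies (20 absence days)
anom_spec <- base
anom_spec$anomaly_days <- seq(10L, by = 18L, length.out = 20L)
anom_spec$anomaly_mode <- "absence"
anom_spec$seed <- 555L
panels <- c(panels, list(generate_household(anom_spec, "HH4")))

# under-instrumented household, excluded later
small_spec <- base
small_spec$n_sensors <- 6L
small_spec$seed <- 777L
panels <- c(panels, list(generate_household(small_spec, "HH5")))

for (p in panels) {
  write_sensor_panel(p,
                     file.path(outdir, paste0(p$household_id, "_activations.csv")),
                     file.path(outdir, paste0(p$household_id, "_labels.csv")))
  cat(sprintf("%s: %d sensors, %d days online, %d anomalous day(s)\n",
              p$household_id, ncol(p$activations), p$days_online,
              sum(p$anomaly_labels)))
}

manifest <- cohort_manifest(panels)
write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
cat("wrote", nrow(manifest), "panels to", outdir, "\n")
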