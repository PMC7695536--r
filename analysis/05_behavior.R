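#!/usr/bin/env Rscript
# Derive the public-health behaviour indicators: each household's regular
# 48-slot activity pattern, wake/sleep times and sleep duration, average
# minutes at home per day of week, and the weekend-vs-weekday contrast.

library(pirvae)

dm_dir <- "results/day_matrices"
model_dir <- "results/models"
outdir <- "results/behavior"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

included <- read.csv(file.path(dm_dir, "included.csv"))
rows <- list()
for (i in seq_len(nrow(included))) {
  hid <- included$household_id[i]
  dm <- read_day_matrix(file.path(dm_dir, paste0(hid, "_days.csv")), hid)
  model <- load_lstm_vae(file.path(model_dir, paste0(hid, "_model.rds")))

  rp <- regular_pattern(model, dm)
  write.csv(data.frame(slot = 0:47, prob = rp$probs, binary = rp$binary),
            file.path(outdir, paste0(hid, "_pattern.csv")), row.names = FALSE)

  bs <- summarize_behavior(rp, dm, minutes_mode = "motion")
  print(bs)
  rows[[hid]] <- behavior_summary_table(bs)
}

summary_tab <- do.call(rbind, rows)
write.csv(summary_tab, file.path(outdir, "behavior_summary.csv"),
          row.names = FALSE)
cat("\nweekend-vs-weekday p-values:\n")
print(summary_tab[, c("household_id", "weekend_vs_weekday_p")], digits = 3)
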