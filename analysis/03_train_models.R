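#!/usr/bin/env Rscript
# Train one LSTM-VAE per included household on a random 80% of its year.
# The model configuration follows the study defaults (2+2 LSTM layers of
# 100 tanh units, latent dimension 7, L1 0.001 on the encoder, Adam,
# mini-batches of 7); training is shortened to 30 epochs, which on these
# clean synthetic schedules is well past loss convergence.

library(pirvae)

dm_dir <- "results/day_matrices"
outdir <- "results/models"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

included <- read.csv(file.path(dm_dir, "included.csv"))
for (i in seq_len(nrow(included))) {
  hid <- included$household_id[i]
  dm <- read_day_matrix(file.path(dm_dir, paste0(hid, "_days.csv")), hid)
  sp <- split_train_test(dm, 0.8, seed = 100L + i)
  cfg <- vae_config(epochs = 30L, seed = 100L + i)
  t0 <- Sys.time()
  model <- fit_lstm_vae(sp$train, cfg)
  mins <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
  save_lstm_vae(model, file.path(outdir, paste0(hid, "_model.rds")))
  write.csv(model$history, file.path(outdir, paste0(hid, "_loss.csv")),
            row.names = FALSE)
  saveRDS(sp, file.path(outdir, paste0(hid, "_split.rds")))
  cat(sprintf(
    "%s: %d train days, %.1f min, reconstruction %.4f -> %.4f (%d epochs)\n",
    hid, nrow(sp$train$X), mins, model$history$reconstruction[1L],
    tail(model$history$reconstruction, 1L), nrow(model$history)))
}
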