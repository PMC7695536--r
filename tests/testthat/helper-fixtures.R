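# Shared fixtures. Trained toy models are cached per test run because several
# files probe the same overfit / two-pattern models.

# Household-A style day: motion in slots 11-44, night run 45..47,0..10.
pattern_hh_a <- function() {
  b <- rep(0L, 48L)
  b[12L:45L] <- 1L
  b
}

# A day_matrix holding n copies of one binary pattern.
pattern_dm <- function(pattern, n, id = "TOY") {
  day_matrix(id, as.Date("2018-01-01") + seq_len(n) - 1L,
             matrix(rep(as.integer(pattern), each = n), n, 48L))
}

toy_cfg <- function(epochs = 80L, ...) {
  vae_config(n_hidden_units = 24L, latent_dim = 4L, epochs = epochs,
             seed = 11L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

# Small model overfit to 50 copies of the household-A pattern.
overfit_fixture <- function() {
  if (is.null(.fixture_cache$overfit)) {
    pat <- pattern_hh_a()
    dm <- pattern_dm(pat, 50L)
    .fixture_cache$overfit <- list(model = fit_lstm_vae(dm, toy_cfg()),
                                   pattern = pat, dm = dm)
  }
  .fixture_cache$overfit
}

# Small model trained on two distinct daily schedules (early riser 5:30-22:30
# vs late riser 9:30-19:30; the patterns differ in 14 slots), 25 copies each.
two_pattern_fixture <- function() {
  if (is.null(.fixture_cache$two)) {
    a <- pattern_hh_a()
    b <- rep(0L, 48L)
    b[20L:39L] <- 1L
    X <- rbind(matrix(rep(a, each = 25L), 25L, 48L),
               matrix(rep(b, each = 25L), 25L, 48L))
    dm <- day_matrix("TOY2", as.Date("2018-01-01") + 0:49, X)
    .fixture_cache$two <- list(model = fit_lstm_vae(dm, toy_cfg(epochs = 150L)),
                               pattern_a = a, pattern_b = b)
  }
  .fixture_cache$two
}

# Noiseless no-departure household: deterministic schedule, slots 14-43.
noiseless_spec <- function(...) {
  household_spec(p_fire_active = 1, p_fire_idle = 0,
                 wake_slot = 14L, sleep_slot = 44L, ...)
}
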