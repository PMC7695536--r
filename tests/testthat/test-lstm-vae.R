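test_that("analytic gradients match finite differences", {
  cfg <- vae_config(n_hidden_units = 6L, latent_dim = 3L, epochs = 0L,
                    seed = 7L)
  set.seed(7)
  params <- pirvae:::vae_init_params(cfg)
  X <- matrix(rbinom(2L * 48L, 1L, 0.4), 2L, 48L)
  eps <- matrix(rnorm(2L * 3L), 2L, 3L)
  loss_fn <- function(p) {
    fw <- pirvae:::vae_forward(p, cfg, X, sample = TRUE, eps = eps)
    48 * mean(pirvae:::bce_per_row(X, fw$dec$Y)) +
      mean(pirvae:::kl_per_row(fw$mu, fw$lv)) +
      cfg$l1_weight * pirvae:::encoder_l1_sum(p, cfg)
  }
  fw <- pirvae:::vae_forward(params, cfg, X, sample = TRUE, eps = eps)
  gr <- pirvae:::vae_backward(params, cfg, fw, X)
  h <- 1e-6
  for (nm in names(params)) {
    for (j in sample(length(params[[nm]]), min(3L, length(params[[nm]])))) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + h
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - h
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("kl_term matches the closed form", {
  expect_equal(kl_term(latent_stats(rep(0, 7), rep(0, 7))), 0)
  expect_equal(kl_term(latent_stats(c(1, 0, 0), c(0, 0, 0))), 0.5)
  # log_var = log(4): KL = 0.5 * (4 - log 4 - 1) per dimension
  expect_equal(kl_term(latent_stats(0, log(4))), 0.5 * (4 - log(4) - 1))
  expect_error(kl_term(latent_stats(c(1, Inf), c(0, 0))), "finite")
})

test_that("kl_term agrees with a Monte-Carlo estimate", {
  set.seed(101)
  for (rep in 1:5) {
    mu <- runif(3, 0.5, 1.5) * sample(c(-1, 1), 3, TRUE)
    lv <- runif(3, -0.6, 0.6)
    closed <- kl_term(latent_stats(mu, lv))
    n <- 2e5
    eps <- matrix(rnorm(n * 3), n, 3)
    z <- sweep(sweep(eps, 2, exp(lv / 2), `*`), 2, mu, `+`)
    # E_q[log q(z) - log p(z)] with q = N(mu, sigma^2), p = N(0, I)
    mc <- mean(rowSums(0.5 * (z^2 - eps^2) - 0.5 * matrix(lv, n, 3, TRUE)))
    expect_equal(closed, mc, tolerance = 0.02)
  }
})

test_that("kl_term is non-negative over random posteriors", {
  set.seed(5)
  for (i in 1:200) {
    expect_gte(kl_term(latent_stats(rnorm(4, 0, 2), rnorm(4, 0, 1.5))), 0)
  }
})

test_that("reconstruction_term matches closed forms", {
  x <- rbinom(48, 1, 0.5)
  expect_equal(reconstruction_term(x, rep(0.5, 48)), log(2))
  expect_equal(reconstruction_term(rep(1, 48), rep(0.9, 48)), -log(0.9))
  near <- abs(x - 1e-7)
  expect_lt(reconstruction_term(x, near), 1e-5)
  expect_error(reconstruction_term(x[-1], rep(0.5, 47)), "48")
})

test_that("total_loss is exactly additive", {
  fx <- overfit_fixture()
  x <- fx$pattern
  stats <- encode_day(fx$model, x)
  xhat <- decode_latent(fx$model, stats$mu)
  lb <- total_loss(x, xhat, stats, fx$model)
  expect_equal(lb$total, lb$reconstruction + lb$kl + lb$l1_penalty)
  m0 <- fx$model
  m0$config$l1_weight <- 0
  lb0 <- total_loss(x, xhat, stats, m0)
  expect_equal(lb0$l1_penalty, 0)
  expect_equal(lb0$total, lb0$reconstruction + lb0$kl)
})

test_that("encoder output is deterministic with the configured shapes", {
  cfg <- vae_config(epochs = 0L, seed = 3L)  # paper defaults: latent dim 7
  dm <- pattern_dm(pattern_hh_a(), 2L)
  model <- fit_lstm_vae(dm, cfg)
  s1 <- encode_day(model, pattern_hh_a())
  s2 <- encode_day(model, pattern_hh_a())
  expect_identical(s1, s2)
  expect_length(s1$mu, 7L)
  expect_length(s1$log_var, 7L)
  expect_true(all(is.finite(c(s1$mu, s1$log_var))))
  expect_error(encode_day(model, rep(1, 47)), "48")
})

test_that("sample_latent implements the reparameterization", {
  stats <- latent_stats(c(2, -1), c(-50, -50))  # variance -> 0: z -> mu
  expect_equal(sample_latent(stats, seed = 1L), stats$mu, tolerance = 1e-9)
  std <- latent_stats(rep(0, 2), rep(0, 2))
  expect_identical(sample_latent(std, seed = 42L), sample_latent(std, seed = 42L))
  draws <- withr::with_seed(8L, {
    t(vapply(1:10000, function(i) sample_latent(std), numeric(2)))
  })
  expect_lt(max(abs(colMeans(draws))), 3 / sqrt(10000))
  expect_lt(max(abs(apply(draws, 2, var) - 1)), 0.05)
})

test_that("decoder output is 48 probabilities", {
  fx <- overfit_fixture()
  z <- rnorm(fx$model$config$latent_dim)
  y <- decode_latent(fx$model, z)
  expect_length(y, 48L)
  expect_true(all(y >= 0 & y <= 1))
  expect_error(decode_latent(fx$model, rnorm(3)), "length")
})

test_that("zero epochs returns the seeded initialization untouched", {
  cfg <- toy_cfg(epochs = 0L)
  model <- fit_lstm_vae(pattern_dm(pattern_hh_a(), 5L), cfg)
  expect_false(model$trained)
  expect_equal(nrow(model$history), 0L)
  ref <- withr::with_seed(cfg$seed, pirvae:::vae_init_params(cfg))
  expect_identical(model$params, ref)
})

test_that("training is reproducible and reduces the loss", {
  dm <- pattern_dm(pattern_hh_a(), 20L)
  cfg <- toy_cfg(epochs = 15L)
  m1 <- fit_lstm_vae(dm, cfg)
  m2 <- fit_lstm_vae(dm, cfg)
  expect_equal(m1$history$total, m2$history$total, tolerance = 1e-12)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 15L)
  expect_lt(m1$history$reconstruction[15L], m1$history$reconstruction[1L])
  # over a full fit the total (recon + KL + L1) also ends below its start
  fx <- overfit_fixture()
  expect_lte(tail(fx$model$history$total, 1L), fx$model$history$total[1L])
})

test_that("the model overfits a single repeated pattern", {
  fx <- overfit_fixture()
  hist <- fx$model$history
  expect_lt(tail(hist$reconstruction, 1L), 0.1)
  expect_lt(tail(hist$reconstruction, 1L), hist$reconstruction[1L])
  # stochastic round trip reproduces the pattern after thresholding
  stats <- encode_day(fx$model, fx$pattern)
  z <- sample_latent(stats, seed = 2L)
  expect_equal(as.integer(decode_latent(fx$model, z) >= 0.5), fx$pattern)
})

test_that("distinct inputs map to distinct latents and reconstructions", {
  fx <- two_pattern_fixture()
  mu_a <- encode_day(fx$model, fx$pattern_a)$mu
  mu_b <- encode_day(fx$model, fx$pattern_b)$mu
  expect_gt(sqrt(sum((mu_a - mu_b)^2)), 1)
  # each cluster centre decodes to its own schedule: at most 2 of 48 slots
  # off (threshold jitter at run boundaries) and far from the other cluster
  dec_a <- as.integer(decode_latent(fx$model, mu_a) >= 0.5)
  dec_b <- as.integer(decode_latent(fx$model, mu_b) >= 0.5)
  expect_lte(sum(dec_a != fx$pattern_a), 2L)
  expect_gte(sum(dec_a != fx$pattern_b), 10L)
  expect_lte(sum(dec_b != fx$pattern_b), 2L)
  expect_gte(sum(dec_b != fx$pattern_a), 10L)
  mu0 <- encode_day(fx$model, rep(0L, 48L))$mu
  mu1 <- encode_day(fx$model, rep(1L, 48L))$mu
  expect_gt(sqrt(sum((mu0 - mu1)^2)), 0)
})

test_that("held-out reconstruction accuracy on a clean schedule is high", {
  dm <- build_day_matrix(generate_household(noiseless_spec(n_days = 80L)))
  sp <- split_train_test(dm, 0.8, seed = 6L)
  model <- fit_lstm_vae(sp$train, toy_cfg(epochs = 30L))
  Y <- pirvae:::vae_reconstruct(model, sp$test$X, posterior = "mean")
  acc <- mean((Y >= 0.5) == (sp$test$X == 1L))
  expect_gte(acc, 0.9)
})

test_that("model checkpoints round-trip through save/load", {
  fx <- overfit_fixture()
  f <- tempfile(fileext = ".rds")
  save_lstm_vae(fx$model, f)
  back <- load_lstm_vae(f)
  expect_identical(back$params, fx$model$params)
  expect_identical(back$config, fx$model$config)
  unlink(f)
})
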