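#' LSTM variational autoencoder configuration
#'
#' Defaults reproduce the study configuration: two 100-unit LSTM layers in
#' both encoder and decoder with tanh activations, a 7-dimensional Gaussian
#' latent, an L1 penalty of 0.001 on the encoder LSTM weights, Adam with
#' learning rate 0.001, mini-batches of 7 sequences and 200 epochs.
#'
#' @param n_hidden_units LSTM hidden units per layer.
#' @param n_recurrent_layers_encoder,n_recurrent_layers_decoder stacked LSTM
#'   layer counts.
#' @param latent_dim dimension of the Gaussian latent z.
#' @param hidden_activation hidden/candidate activation (only `"tanh"`, the
#'   standard cell, is implemented).
#' @param l1_weight L1 penalty weight on the encoder LSTM input and recurrent
#'   kernels.
#' @param batch_size mini-batch size (the last short batch is kept).
#' @param epochs training epochs; 0 returns the initialized model untrained.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param lr_decay time-based decay: lr_epoch = lr / (1 + decay * epoch).
#' @param seed controls weight initialization, shuffling and latent sampling.
#' @param n_mc posterior samples averaged per day when scoring.
#' @param grad_clip optional global gradient-norm ceiling; `Inf` (the
#'   default, matching standard Adam practice) disables clipping.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(n_hidden_units = 100L,
                       n_recurrent_layers_encoder = 2L,
                       n_recurrent_layers_decoder = 2L,
                       latent_dim = 7L,
                       hidden_activation = "tanh",
                       l1_weight = 0.001,
                       batch_size = 7L,
                       epochs = 200L,
                       optimizer = "adam",
                       learning_rate = 0.001,
                       lr_decay = 0,
                       seed = 42L,
                       n_mc = 1L,
                       grad_clip = Inf) {
  cfg <- structure(list(
    n_hidden_units = as.integer(n_hidden_units),
    n_recurrent_layers_encoder = as.integer(n_recurrent_layers_encoder),
    n_recurrent_layers_decoder = as.integer(n_recurrent_layers_decoder),
    latent_dim = as.integer(latent_dim),
    hidden_activation = match.arg(hidden_activation, "tanh"),
    l1_weight = l1_weight,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    optimizer = match.arg(optimizer, "adam"),
    learning_rate = learning_rate,
    lr_decay = lr_decay,
    seed = as.integer(seed),
    n_mc = as.integer(n_mc),
    grad_clip = grad_clip
  ), class = "vae_config")
  with(cfg, {
    if (n_hidden_units < 1L || latent_dim < 1L || batch_size < 1L ||
        n_recurrent_layers_encoder < 1L || n_recurrent_layers_decoder < 1L) {
      stop("all model size counts must be positive")
    }
    if (epochs < 0L) stop("epochs must be >= 0")
    if (learning_rate <= 0) stop("learning_rate must be positive")
    if (l1_weight < 0 || lr_decay < 0) stop("l1_weight and lr_decay must be >= 0")
  })
  cfg
}

N_SLOTS <- 48L
PROB_EPS <- 1e-7  # clipping bound for reconstruction probabilities

vae_init_params <- function(cfg) {
  H <- cfg$n_hidden_units
  L <- cfg$latent_dim
  p <- list()
  d_in <- 1L
  for (l in seq_len(cfg$n_recurrent_layers_encoder)) {
    cell <- init_lstm_cell(d_in, H)
    p[[paste0("enc", l, ".W")]] <- cell$W
    p[[paste0("enc", l, ".U")]] <- cell$U
    p[[paste0("enc", l, ".b")]] <- cell$b
    d_in <- H
  }
  p[["mu.W"]] <- glorot_uniform(H, L); p[["mu.b"]] <- rep(0, L)
  p[["lv.W"]] <- glorot_uniform(H, L); p[["lv.b"]] <- rep(0, L)
  d_in <- L
  for (l in seq_len(cfg$n_recurrent_layers_decoder)) {
    cell <- init_lstm_cell(d_in, H)
    p[[paste0("dec", l, ".W")]] <- cell$W
    p[[paste0("dec", l, ".U")]] <- cell$U
    p[[paste0("dec", l, ".b")]] <- cell$b
    d_in <- H
  }
  p[["out.W"]] <- glorot_uniform(H, 1L); p[["out.b"]] <- 0
  p
}

get_cell <- function(params, prefix) {
  list(W = params[[paste0(prefix, ".W")]],
       U = params[[paste0(prefix, ".U")]],
       b = params[[paste0(prefix, ".b")]])
}

# Encoder stack: X (B x 48 binary matrix) -> per-layer caches, final hidden
# state and the latent Gaussian parameters.
encoder_forward <- function(params, cfg, X) {
  B <- nrow(X)
  inp <- array(X, c(B, N_SLOTS, 1L))
  fwds <- vector("list", cfg$n_recurrent_layers_encoder)
  for (l in seq_len(cfg$n_recurrent_layers_encoder)) {
    fwds[[l]] <- lstm_seq_forward(inp, get_cell(params, paste0("enc", l)))
    inp <- fwds[[l]]$H
  }
  hT <- matrix(inp[, N_SLOTS, ], B, cfg$n_hidden_units)
  mu <- hT %*% params[["mu.W"]] +
    matrix(params[["mu.b"]], B, cfg$latent_dim, byrow = TRUE)
  lv <- hT %*% params[["lv.W"]] +
    matrix(params[["lv.b"]], B, cfg$latent_dim, byrow = TRUE)
  list(fwds = fwds, hT = hT, mu = mu, lv = lv)
}

# Decoder stack: z (B x latent_dim) repeated over the 48 slots -> per-slot
# motion probabilities Y (B x 48).
decoder_forward <- function(params, cfg, z) {
  B <- nrow(z)
  Za <- array(0, c(B, N_SLOTS, cfg$latent_dim))
  for (t in seq_len(N_SLOTS)) Za[, t, ] <- z
  fwds <- vector("list", cfg$n_recurrent_layers_decoder)
  inp <- Za
  for (l in seq_len(cfg$n_recurrent_layers_decoder)) {
    fwds[[l]] <- lstm_seq_forward(inp, get_cell(params, paste0("dec", l)))
    inp <- fwds[[l]]$H
  }
  Hflat <- matrix(inp, B * N_SLOTS, cfg$n_hidden_units)
  logits <- matrix(Hflat %*% params[["out.W"]] + params[["out.b"]], B, N_SLOTS)
  list(fwds = fwds, Hflat = Hflat, logits = logits, Y = sigmoid(logits))
}

# One full pass: encode, reparameterize (eps ~ N(0,I) supplied by caller or
# drawn from the current RNG stream), decode.
vae_forward <- function(params, cfg, X, sample = TRUE, eps = NULL) {
  enc <- encoder_forward(params, cfg, X)
  B <- nrow(X)
  if (sample) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
    z <- enc$mu + exp(enc$lv / 2) * eps
  } else {
    eps <- NULL
    z <- enc$mu
  }
  dec <- decoder_forward(params, cfg, z)
  c(enc, list(eps = eps, z = z, dec = dec))
}

# Per-sample mean binary cross-entropy over the 48 slots.
bce_per_row <- function(X, Y) {
  Yc <- pmin(pmax(Y, PROB_EPS), 1 - PROB_EPS)
  -rowMeans(X * log(Yc) + (1 - X) * log(1 - Yc))
}

# Per-sample KL( N(mu, sigma^2) || N(0, I) ), summed over latent dimensions.
kl_per_row <- function(mu, lv) {
  -0.5 * rowSums(1 + lv - mu * mu - exp(lv))
}

encoder_l1_sum <- function(params, cfg) {
  s <- 0
  for (l in seq_len(cfg$n_recurrent_layers_encoder)) {
    s <- s + sum(abs(params[[paste0("enc", l, ".W")]])) +
      sum(abs(params[[paste0("enc", l, ".U")]]))
  }
  s
}

# Gradients of the training objective w.r.t. every parameter. The objective
# is the negative ELBO with a per-slot Bernoulli likelihood — binary
# cross-entropy SUMMED over the 48 slots — plus the KL term and L1 penalty,
# averaged over the batch. (Per-day scores reported elsewhere use the mean
# over slots; the two differ only by the constant factor 48.)
vae_backward <- function(params, cfg, fw, X) {
  B <- nrow(X)
  H <- cfg$n_hidden_units
  grads <- lapply(params, function(p) p * 0)

  dlogits <- (fw$dec$Y - X) / B
  dlog_flat <- matrix(as.vector(dlogits), B * N_SLOTS, 1L)
  grads[["out.W"]] <- crossprod(fw$dec$Hflat, dlog_flat)
  grads[["out.b"]] <- sum(dlog_flat)
  dH_top <- array(dlog_flat %*% t(params[["out.W"]]), c(B, N_SLOTS, H))

  dH <- dH_top
  for (l in rev(seq_len(cfg$n_recurrent_layers_decoder))) {
    prefix <- paste0("dec", l)
    bk <- lstm_seq_backward(dH, fw$dec$fwds[[l]], get_cell(params, prefix))
    grads[[paste0(prefix, ".W")]] <- bk$dW
    grads[[paste0(prefix, ".U")]] <- bk$dU
    grads[[paste0(prefix, ".b")]] <- bk$db
    dH <- bk$dX
  }
  # dH is now B x 48 x latent_dim: gradient w.r.t. the repeated z
  dz <- matrix(0, B, cfg$latent_dim)
  for (t in seq_len(N_SLOTS)) dz <- dz + matrix(dH[, t, ], B, cfg$latent_dim)

  dmu <- dz + fw$mu / B
  dlv <- 0.5 * (exp(fw$lv) - 1) / B
  if (!is.null(fw$eps)) dlv <- dlv + dz * fw$eps * 0.5 * exp(fw$lv / 2)

  grads[["mu.W"]] <- crossprod(fw$hT, dmu)
  grads[["mu.b"]] <- colSums(dmu)
  grads[["lv.W"]] <- crossprod(fw$hT, dlv)
  grads[["lv.b"]] <- colSums(dlv)
  dhT <- tcrossprod(dmu, params[["mu.W"]]) + tcrossprod(dlv, params[["lv.W"]])

  dH <- array(0, c(B, N_SLOTS, H))
  dH[, N_SLOTS, ] <- dhT
  for (l in rev(seq_len(cfg$n_recurrent_layers_encoder))) {
    prefix <- paste0("enc", l)
    bk <- lstm_seq_backward(dH, fw$fwds[[l]], get_cell(params, prefix))
    grads[[paste0(prefix, ".W")]] <- bk$dW +
      cfg$l1_weight * sign(params[[paste0(prefix, ".W")]])
    grads[[paste0(prefix, ".U")]] <- bk$dU +
      cfg$l1_weight * sign(params[[paste0(prefix, ".U")]])
    grads[[paste0(prefix, ".b")]] <- bk$db
    dH <- bk$dX
  }
  grads
}

#' Train the LSTM-VAE on a day matrix
#'
#' Minimizes the negative evidence lower bound with a per-slot Bernoulli
#' likelihood — binary cross-entropy between each day and its stochastic
#' reconstruction, summed over the 48 slots — plus the closed-form KL
#' divergence from the latent posterior to the standard-normal prior and the
#' L1 penalty on the encoder LSTM kernels. Mini-batch Adam; sequence order
#' is reshuffled every epoch; everything is reproducible under
#' `config$seed`. The loss history reports the reconstruction term as the
#' per-slot mean so values are comparable across configurations.
#'
#' @param train_dm a `day_matrix` of training days.
#' @param config a [vae_config()].
#' @return object of class `lstm_vae` with elements `config`, `params`,
#'   `trained`, and `history` (one row per epoch: `epoch`, `reconstruction`,
#'   `kl`, `l1`, `total`).
#' @export
fit_lstm_vae <- function(train_dm, config = vae_config()) {
  if (!inherits(train_dm, "day_matrix")) stop("train_dm must be a day_matrix")
  X_all <- train_dm$X
  n <- nrow(X_all)
  if (n < 1L) stop("training day matrix is empty")
  cfg <- config
  history <- vector("list", cfg$epochs)

  params <- NULL
  withr::with_seed(cfg$seed, {
    params <- vae_init_params(cfg)
    opt <- adam_init(params)
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- cfg$learning_rate / (1 + cfg$lr_decay * (ep - 1))
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_rec <- ep_kl <- ep_l1 <- ep_tot <- 0
      for (bi in batches) {
        Xb <- X_all[bi, , drop = FALSE]
        B <- nrow(Xb)
        eps <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
        fw <- vae_forward(params, cfg, Xb, sample = TRUE, eps = eps)
        rec <- mean(bce_per_row(Xb, fw$dec$Y))  # reported per-slot mean
        kl <- mean(kl_per_row(fw$mu, fw$lv))
        l1 <- cfg$l1_weight * encoder_l1_sum(params, cfg)
        tot <- rec + kl + l1
        if (!is.finite(tot)) {
          stop("training diverged (non-finite loss) at epoch ", ep)
        }
        grads <- vae_backward(params, cfg, fw, Xb)
        grads <- clip_global_norm(grads, cfg$grad_clip)
        upd <- adam_step(params, grads, opt, lr_ep)
        params <- upd$params
        opt <- upd$opt
        w <- B / n
        ep_rec <- ep_rec + w * rec
        ep_kl <- ep_kl + w * kl
        ep_l1 <- ep_l1 + w * l1
        ep_tot <- ep_tot + w * tot
      }
      history[[ep]] <- c(epoch = ep, reconstruction = ep_rec, kl = ep_kl,
                         l1 = ep_l1, total = ep_tot)
    }
  })

  hist_df <- if (cfg$epochs > 0L) {
    as.data.frame(do.call(rbind, history))
  } else {
    data.frame(epoch = integer(0), reconstruction = numeric(0),
               kl = numeric(0), l1 = numeric(0), total = numeric(0))
  }
  structure(list(config = cfg, params = params, trained = cfg$epochs > 0L,
                 history = hist_df),
            class = "lstm_vae")
}

#' @export
print.lstm_vae <- function(x, ...) {
  cat("<lstm_vae> ", x$config$n_recurrent_layers_encoder, "+",
      x$config$n_recurrent_layers_decoder, " LSTM layers x ",
      x$config$n_hidden_units, " units, latent dim ", x$config$latent_dim,
      if (x$trained) paste0(", trained ", nrow(x$history), " epochs")
      else ", untrained", "\n", sep = "")
  invisible(x)
}

check_day_vector <- function(day) {
  day <- as.numeric(day)
  if (length(day) != N_SLOTS) stop("a day must have exactly 48 slots")
  if (!all(day == 0 | day == 1)) stop("day slots must be binary")
  day
}

#' Encode a day into its latent Gaussian posterior
#'
#' Runs the encoder LSTM stack over the 48-slot sequence and maps the final
#' hidden state through the two linear heads giving the posterior mean and
#' log-variance. Deterministic given the model weights.
#'
#' @param model a trained or initialized `lstm_vae`.
#' @param day binary vector of length 48.
#' @return object of class `latent_stats` with numeric vectors `mu` and
#'   `log_var` of length `latent_dim`.
#' @export
encode_day <- function(model, day) {
  day <- check_day_vector(day)
  enc <- encoder_forward(model$params, model$config, matrix(day, 1L))
  latent_stats(as.numeric(enc$mu), as.numeric(enc$lv))
}

#' Latent Gaussian parameters
#'
#' @param mu,log_var finite numeric vectors of equal length.
#' @return object of class `latent_stats`.
#' @export
latent_stats <- function(mu, log_var) {
  if (length(mu) != length(log_var)) stop("mu and log_var must have equal length")
  if (!all(is.finite(mu)) || !all(is.finite(log_var))) {
    stop("latent statistics must be finite")
  }
  structure(list(mu = as.numeric(mu), log_var = as.numeric(log_var)),
            class = "latent_stats")
}

#' Reparameterized draw from the latent posterior
#'
#' z = mu + exp(log_var / 2) * eps with eps ~ N(0, I).
#'
#' @param stats a [latent_stats()].
#' @param seed optional seed; when given the draw is reproducible and the
#'   global RNG state is left untouched.
#' @return numeric latent vector z.
#' @export
sample_latent <- function(stats, seed = NULL) {
  if (!inherits(stats, "latent_stats")) stop("stats must be latent_stats")
  draw <- function() stats$mu + exp(stats$log_var / 2) * stats::rnorm(length(stats$mu))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Decode a latent vector into per-slot motion probabilities
#'
#' @param model an `lstm_vae`.
#' @param z numeric latent vector of length `latent_dim`.
#' @return numeric vector of 48 probabilities in [0, 1].
#' @export
decode_latent <- function(model, z) {
  if (length(z) != model$config$latent_dim) {
    stop("z must have length ", model$config$latent_dim)
  }
  dec <- decoder_forward(model$params, model$config, matrix(as.numeric(z), 1L))
  as.numeric(dec$Y)
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' KL( N(mu, diag(sigma^2)) || N(0, I) ) =
#'   -1/2 * sum_d (1 + log_var_d - mu_d^2 - exp(log_var_d)); always >= 0,
#' zero exactly when the posterior equals the prior.
#'
#' @param stats a [latent_stats()].
#' @return non-negative scalar.
#' @export
kl_term <- function(stats) {
  if (!inherits(stats, "latent_stats")) stats <- do.call(latent_stats, stats)
  as.numeric(kl_per_row(matrix(stats$mu, 1L), matrix(stats$log_var, 1L)))
}

#' Per-slot binary cross-entropy reconstruction error
#'
#' Mean over the 48 slots of -[x log(x_hat) + (1 - x) log(1 - x_hat)], with
#' probabilities clipped to [1e-7, 1 - 1e-7].
#'
#' @param x binary vector of length 48.
#' @param x_hat probability vector of length 48.
#' @return non-negative scalar.
#' @export
reconstruction_term <- function(x, x_hat) {
  x <- check_day_vector(x)
  if (length(x_hat) != N_SLOTS) stop("x and x_hat must both have 48 slots")
  as.numeric(bce_per_row(matrix(x, 1L), matrix(as.numeric(x_hat), 1L)))
}

#' Full loss breakdown for one day
#'
#' total = reconstruction + KL + l1_weight * sum(|encoder LSTM kernels|).
#'
#' @param x binary day, `x_hat` its reconstruction probabilities.
#' @param x_hat probability vector of length 48.
#' @param stats the day's [latent_stats()].
#' @param model the `lstm_vae` whose encoder weights enter the L1 penalty.
#' @return object of class `loss_breakdown` with fields `reconstruction`,
#'   `kl`, `l1_penalty`, `total`.
#' @export
total_loss <- function(x, x_hat, stats, model) {
  rec <- reconstruction_term(x, x_hat)
  kl <- kl_term(stats)
  l1 <- model$config$l1_weight * encoder_l1_sum(model$params, model$config)
  structure(list(reconstruction = rec, kl = kl, l1_penalty = l1,
                 total = rec + kl + l1),
            class = "loss_breakdown")
}

#' Save / load a trained model
#'
#' The checkpoint is a single-file archive embedding the configuration,
#' weights and training history.
#'
#' @param model an `lstm_vae`.
#' @param file checkpoint path.
#' @return `save_lstm_vae` returns `model` invisibly; `load_lstm_vae` the model.
#' @export
save_lstm_vae <- function(model, file) {
  saveRDS(model, file)
  invisible(model)
}

#' @rdname save_lstm_vae
#' @export
load_lstm_vae <- function(file) {
  model <- readRDS(file)
  if (!inherits(model, "lstm_vae")) stop("not an lstm_vae checkpoint")
  model
}

# Batched reconstruction used by the anomaly and behavior modules.
# posterior = "sample": one reparameterized draw per row (current RNG stream);
# posterior = "mean":   z = mu, no sampling noise.
vae_reconstruct <- function(model, X, posterior = c("sample", "mean")) {
  posterior <- match.arg(posterior)
  fw <- vae_forward(model$params, model$config, X,
                    sample = posterior == "sample")
  fw$dec$Y
}
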