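# Stacked-LSTM primitives: forward pass with caches and full backpropagation
# through time, vectorized over the batch. Standard cell with gates i, f, o,
# candidate g and memory cell c_t updating the hidden state h_t:
#   a      = x W + h_{t-1} U + b            (a split into 4 gate pre-activations)
#   i,f,o  = sigmoid(a_i), sigmoid(a_f), sigmoid(a_o)
#   g      = tanh(a_g)
#   c_t    = f * c_{t-1} + i * g
#   h_t    = o * tanh(c_t)
# Gate block order in W/U/b columns: [i | f | g | o]. Forget-gate bias
# initialized to 1 (the usual trick against early vanishing memory).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

# Random orthogonal matrix (rows orthonormal when n_in <= n_out), the
# standard initializer for recurrent kernels: preserves hidden-state norm
# across steps, which matters for remembering position in long runs.
orthogonal_init <- function(n_in, n_out) {
  big <- max(n_in, n_out)
  small <- min(n_in, n_out)
  qr_ <- qr(matrix(stats::rnorm(big * small), big, small))
  q <- qr.Q(qr_)
  # fix the sign convention so the distribution is uniform (Haar)
  q <- q %*% diag(sign(diag(qr.R(qr_))), small, small)
  if (n_in <= n_out) t(q[seq_len(n_out), seq_len(n_in), drop = FALSE])
  else q[seq_len(n_in), seq_len(n_out), drop = FALSE]
}

init_lstm_cell <- function(d_in, H) {
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- 1
  list(W = glorot_uniform(d_in, 4L * H), U = orthogonal_init(H, 4L * H), b = b)
}

# X: B x T x D array. Returns hidden states H (B x T x H) plus the caches
# needed by lstm_seq_backward.
lstm_seq_forward <- function(X, cell) {
  B <- dim(X)[1L]; TT <- dim(X)[2L]; D <- dim(X)[3L]
  H <- length(cell$b) %/% 4L
  Hs <- array(0, c(B, TT, H))
  Cs <- array(0, c(B, TT, H))
  Gs <- array(0, c(B, TT, 4L * H))
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  bmat <- matrix(cell$b, B, 4L * H, byrow = TRUE)
  i_ix <- 1L:H; f_ix <- (H + 1L):(2L * H)
  g_ix <- (2L * H + 1L):(3L * H); o_ix <- (3L * H + 1L):(4L * H)
  for (t in seq_len(TT)) {
    xt <- X[, t, ]; dim(xt) <- c(B, D)
    a <- xt %*% cell$W + h %*% cell$U + bmat
    i <- sigmoid(a[, i_ix, drop = FALSE])
    f <- sigmoid(a[, f_ix, drop = FALSE])
    g <- tanh(a[, g_ix, drop = FALSE])
    o <- sigmoid(a[, o_ix, drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    Hs[, t, ] <- h
    Cs[, t, ] <- cc
    Gs[, t, ] <- cbind(i, f, g, o)
  }
  list(H = Hs, C = Cs, G = Gs, X = X)
}

# dH: gradient of the loss w.r.t. every hidden state (B x T x H). Returns
# parameter gradients and dX, the gradient w.r.t. the layer input sequence.
lstm_seq_backward <- function(dH, fwd, cell) {
  B <- dim(fwd$X)[1L]; TT <- dim(fwd$X)[2L]; D <- dim(fwd$X)[3L]
  H <- length(cell$b) %/% 4L
  dW <- matrix(0, D, 4L * H)
  dU <- matrix(0, H, 4L * H)
  db <- rep(0, 4L * H)
  dX <- array(0, c(B, TT, D))
  dh_carry <- matrix(0, B, H)
  dc_carry <- matrix(0, B, H)
  i_ix <- 1L:H; f_ix <- (H + 1L):(2L * H)
  g_ix <- (2L * H + 1L):(3L * H); o_ix <- (3L * H + 1L):(4L * H)
  for (t in TT:1L) {
    g4 <- fwd$G[, t, ]; dim(g4) <- c(B, 4L * H)
    i <- g4[, i_ix, drop = FALSE]; f <- g4[, f_ix, drop = FALSE]
    g <- g4[, g_ix, drop = FALSE]; o <- g4[, o_ix, drop = FALSE]
    tc <- fwd$C[, t, ]; dim(tc) <- c(B, H); tc <- tanh(tc)
    if (t > 1L) {
      c_prev <- fwd$C[, t - 1L, ]; dim(c_prev) <- c(B, H)
      h_prev <- fwd$H[, t - 1L, ]; dim(h_prev) <- c(B, H)
    } else {
      c_prev <- h_prev <- matrix(0, B, H)
    }
    dh <- dH[, t, ]; dim(dh) <- c(B, H); dh <- dh + dh_carry
    do <- dh * tc
    dc <- dc_carry + dh * o * (1 - tc * tc)
    di <- dc * g
    df <- dc * c_prev
    dg <- dc * i
    dc_carry <- dc * f
    da <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g * g), do * o * (1 - o))
    xt <- fwd$X[, t, ]; dim(xt) <- c(B, D)
    dW <- dW + crossprod(xt, da)
    dU <- dU + crossprod(h_prev, da)
    db <- db + colSums(da)
    dh_carry <- tcrossprod(da, cell$U)
    dX[, t, ] <- tcrossprod(da, cell$W)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# Adam with bias correction; lr passed per step to allow time decay.
adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)  # p*0 preserves shape exactly
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}
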