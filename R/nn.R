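## Internal layer machinery for the CNN-BiLSTM.  No deep-learning
## framework is available in this stack, so forward and backward passes
## are written out explicitly: convolutions run through the compiled
## im2col/GEMM kernels in src/, everything else is vectorised R.
## Activations live as C x (B*T) matrices (each sample's time steps
## contiguous); dense-layer activations as B x units matrices.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

## ---- batch normalisation (per channel = per row) --------------------------

bn_forward <- function(x, gamma, beta, run_mean, run_var, eps, momentum,
                       training) {
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    inv_std <- 1 / sqrt(v + eps)
    xhat <- (x - mu) * inv_std
    y <- xhat * gamma + beta
    list(y = y, xhat = xhat, inv_std = inv_std,
         run_mean = momentum * run_mean + (1 - momentum) * mu,
         run_var = momentum * run_var + (1 - momentum) * v)
  } else {
    inv_std <- 1 / sqrt(run_var + eps)
    y <- ((x - run_mean) * inv_std) * gamma + beta
    list(y = y)
  }
}

bn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  n <- ncol(dy)
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dx <- (cache$inv_std / n) *
    (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- PReLU (one slope per channel / unit) ---------------------------------

# `byrow = TRUE` for C x (B*T) activations (alpha recycles down columns),
# FALSE for B x units dense activations
prelu_forward <- function(x, alpha, byrow = TRUE) {
  a <- if (byrow) alpha else rep(alpha, each = nrow(x))
  list(y = pmax(x, 0) + a * pmin(x, 0))
}

prelu_backward <- function(dy, x, alpha, cache, byrow = TRUE) {
  a <- if (byrow) alpha else rep(alpha, each = nrow(x))
  pos <- x > 0
  dyneg <- dy * !pos
  dx <- dy * pos + a * dyneg
  dneg <- dyneg * x
  dalpha <- if (byrow) rowSums(dneg) else colSums(dneg)
  list(dx = dx, dalpha = dalpha)
}

## ---- max pooling (size 2, stride 2 along time; floor rule) ----------------

pool_indices <- function(B, T) {
  To <- T %/% 2L
  base <- rep((0:(B - 1L)) * T, each = To)
  within <- rep(seq(1L, 2L * To, by = 2L), times = B)
  list(i1 = base + within, i2 = base + within + 1L, To = To)
}

maxpool_forward <- function(x, idx) {
  x1 <- x[, idx$i1, drop = FALSE]
  x2 <- x[, idx$i2, drop = FALSE]
  mask <- x1 >= x2
  y <- x2
  y[mask] <- x1[mask]
  list(y = y, mask = mask)
}

maxpool_backward <- function(dy, cache, idx, ncol_in) {
  dx <- matrix(0, nrow(dy), ncol_in)
  d1 <- dy; d1[!cache$mask] <- 0
  d2 <- dy; d2[cache$mask] <- 0
  dx[, idx$i1] <- d1
  dx[, idx$i2] <- d2
  dx
}

## ---- LSTM (single direction) ----------------------------------------------
## Gate order i, f, g, o.  Input: list of T matrices (B x Cin); returns the
## final hidden state (B x units) plus the per-step cache for BPTT.

lstm_forward <- function(xs, Wx, Wh, b) {
  Tn <- length(xs)
  B <- nrow(xs[[1]])
  u <- ncol(Wh) / 4L
  H <- matrix(0, B, u)
  C <- matrix(0, B, u)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Z <- xs[[t]] %*% Wx + H %*% Wh
    Z <- sweep(Z, 2, b, "+")
    i <- sigmoid(Z[, 1:u, drop = FALSE])
    f <- sigmoid(Z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(Z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigmoid(Z[, (3 * u + 1):(4 * u), drop = FALSE])
    C_prev <- C
    C <- f * C + i * g
    tc <- tanh(C)
    cache[[t]] <- list(x = xs[[t]], i = i, f = f, g = g, o = o,
                       C_prev = C_prev, tc = tc, H_prev = H)
    H <- o * tc
  }
  list(h = H, cache = cache)
}

lstm_backward <- function(dH_last, cache, Wx, Wh) {
  Tn <- length(cache)
  u <- ncol(dH_last)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * u)
  dH <- dH_last
  dC <- matrix(0, nrow(dH), u)
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    do_ <- dH * cc$tc
    dC <- dC + dH * cc$o * (1 - cc$tc^2)
    di <- dC * cc$g
    df <- dC * cc$C_prev
    dg <- dC * cc$i
    dC <- dC * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dZ)
    dWh <- dWh + crossprod(cc$H_prev, dZ)
    db <- db + colSums(dZ)
    dxs[[t]] <- dZ %*% t(Wx)
    dH <- dZ %*% t(Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

## ---- softmax cross-entropy -------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, opt) {
  state$t <- state$t + 1L
  lr_t <- opt$learning_rate *
    sqrt(1 - opt$beta2^state$t) / (1 - opt$beta1^state$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- opt$beta1 * state$m[[nm]] + (1 - opt$beta1) * g
    state$v[[nm]] <- opt$beta2 * state$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + opt$epsilon)
  }
  list(params = params, state = state)
}
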