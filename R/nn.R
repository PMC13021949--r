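# Internal neural-network primitives: initialization, batch normalization,
# softmax/cross-entropy, and the Adam optimizer. All dense base-R matrix ops;
# gradients are verified against finite differences in the test suite.

glorot_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

relu <- function(x) x * (x > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch norm over rows (each column a feature channel).
# training: batch statistics (biased variance), running stats updated in the
# returned element `rstat`; inference: running statistics, purely affine.
bn_forward <- function(x, gamma, beta, rmean, rvar, training) {
  if (training) {
    m <- nrow(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colSums(xc^2) / m
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, inv, `*`)
    out <- sweep(xhat, 2, gamma, `*`)
    out <- sweep(out, 2, beta, `+`)
    list(out = out,
         cache = list(xhat = xhat, inv = inv, xc = xc, gamma = gamma, m = m),
         rstat = list(mean = (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu,
                      var  = (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * v))
  } else {
    inv <- 1 / sqrt(rvar + BN_EPS)
    xhat <- sweep(sweep(x, 2, rmean), 2, inv, `*`)
    out <- sweep(xhat, 2, gamma, `*`)
    out <- sweep(out, 2, beta, `+`)
    list(out = out, cache = list(scale = gamma * inv, xhat_inf = xhat),
         rstat = NULL)
  }
}

bn_backward <- function(dout, cache) {
  if (!is.null(cache$scale)) {           # inference mode: affine per column
    return(list(dx = sweep(dout, 2, cache$scale, `*`),
                dgamma = colSums(dout * cache$xhat_inf),
                dbeta = colSums(dout)))
  }
  m <- cache$m
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, `*`)
  # dx = inv/m * (m*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- m * dxhat
  dx <- sweep(dx, 2, s1)
  dx <- dx - sweep(cache$xhat, 2, s2, `*`)
  dx <- sweep(dx, 2, cache$inv / m, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# inverted dropout; draws from the current RNG stream
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(out = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
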