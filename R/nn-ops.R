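# Low-level differentiable building blocks. Each *_fwd returns the output
# plus whatever the matching *_bwd needs; gradients are hand-derived and
# verified against finite differences in the test suite. Activation arrays
# are (X, Y, Z, C, T) with frames along T acting as the batch.

conv3d_fwd <- function(x, w, b) {
  d <- dim(x)
  if (length(d) != 5) stop_shape("conv3d expects a 5D array")
  if (nrow(w) != 27 * d[4])
    stop_shape("conv weight rows (%d) != 27 * input channels (%d)", nrow(w), 27 * d[4])
  conv3d_fwd_cpp(x, as.integer(d), w, b)
}

conv3d_bwd <- function(x, w, dy) {
  out <- conv3d_bwd_cpp(x, as.integer(dim(x)), w, dy)
  out$db <- as.vector(out$db)
  out
}

avgpool3d_fwd <- function(x) avgpool3d_fwd_cpp(x, as.integer(dim(x)))
avgpool3d_bwd <- function(dy, dims_in) avgpool3d_bwd_cpp(dy, as.integer(dims_in))

# --- batch normalization over (voxels x frames) per channel ----------------

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels))
}

bn_state_init <- function(channels) {
  list(mean = rep(0, channels), var = rep(1, channels))
}

# x: (X,Y,Z,C,T). Returns y plus cache; `state` holds running statistics
# (momentum 0.9), used verbatim when train = FALSE.
bn_fwd <- function(x, pars, state, train = TRUE, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 3, 5, 4)), ncol = d[4])
  if (train) {
    mu <- colMeans(m)
    ctr <- sweep(m, 2L, mu)
    v <- colMeans(ctr^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    ctr <- sweep(m, 2L, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(ctr, 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, pars$gamma, `*`), 2L, pars$beta, `+`)
  dim(y) <- c(d[1:3], d[5], d[4])
  list(y = aperm(y, c(1, 2, 3, 5, 4)),
       cache = list(xhat = xhat, inv = inv, dims = d, train = train),
       state = state)
}

bn_bwd <- function(dy, cache, pars) {
  d <- cache$dims
  dm <- matrix(aperm(dy, c(1, 2, 3, 5, 4)), ncol = d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, pars$gamma, `*`)
  if (cache$train) {
    n <- nrow(dm)
    dx <- sweep(
      sweep(dxhat, 2L, colSums(dxhat) / n) -
        sweep(xhat, 2L, colSums(dxhat * xhat) / n, `*`),
      2L, cache$inv, `*`)
  } else {
    dx <- sweep(dxhat, 2L, cache$inv, `*`)
  }
  dim(dx) <- c(d[1:3], d[5], d[4])
  list(dx = aperm(dx, c(1, 2, 3, 5, 4)), dgamma = dgamma, dbeta = dbeta)
}

# --- dense layers -----------------------------------------------------------

linear_init <- function(fan_in, fan_out, scale = sqrt(2 / fan_in)) {
  list(w = matrix(rnorm(fan_in * fan_out, sd = scale), fan_in, fan_out),
       b = rep(0, fan_out))
}

linear_fwd <- function(x, layer) sweep(x %*% layer$w, 2L, layer$b, `+`)

# dy: same shape as output; x: input. Returns grads and dx.
linear_bwd <- function(dy, x, layer) {
  list(dx = dy %*% t(layer$w), dw = crossprod(x, dy), db = colSums(dy))
}

# --- layer normalization per row -------------------------------------------

ln_init <- function(width) list(gain = rep(1, width), bias = rep(0, width))

ln_fwd <- function(x, pars, eps = 1e-6) {
  mu <- rowMeans(x)
  ctr <- x - mu
  v <- rowMeans(ctr^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- ctr * inv
  y <- sweep(sweep(xhat, 2L, pars$gain, `*`), 2L, pars$bias, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(dy, cache, pars) {
  xhat <- cache$xhat
  q <- ncol(dy)
  dgain <- colSums(dy * xhat)
  dbias <- colSums(dy)
  dxhat <- sweep(dy, 2L, pars$gain, `*`)
  dx <- (dxhat - rowMeans(dxhat) -
           xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgain = dgain, dbias = dbias)
}

# --- Adam over arbitrarily nested parameter lists ---------------------------

adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# elementwise sum of two identically shaped nested gradient lists
grad_add <- function(a, b) {
  if (is.list(a)) Map(grad_add, a, b) else a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) lapply(a, grad_scale, s = s) else a * s
}

grad_zero <- function(params) {
  if (is.list(params)) lapply(params, grad_zero) else params * 0
}
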