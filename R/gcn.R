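#' Symmetric degree normalization of a connectivity matrix
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of
#' `A + I`, the propagation operator of a Kipf-Welling graph convolution.
#' Empirical Pearson matrices contain negative correlations, which degree
#' normalization cannot accommodate, so with `empirical = TRUE` off-diagonal
#' entries `r` are first rescaled to `[0, 1]` via `(r + 1) / 2`.
#'
#' @param a symmetric `n_roi` x `n_roi` connectivity matrix.
#' @param empirical rescale off-diagonal Pearson values into `[0, 1]` first.
#' @return the normalized operator, symmetric whenever `a` is.
#' @export
normalize_adjacency <- function(a, empirical = FALSE) {
  if (nrow(a) != ncol(a)) stop_shape("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-9) stop("adjacency must be symmetric", call. = FALSE)
  if (empirical) {
    d0 <- diag(a)
    a <- (a + 1) / 2
    diag(a) <- d0
  }
  b <- a + diag(nrow(a))
  deg <- rowSums(b)
  if (any(deg < 1e-8)) {
    warning("zero-degree node: flooring degree at 1e-8")
    deg <- pmax(deg, 1e-8)
  }
  s <- 1 / sqrt(deg)
  b * outer(s, s)
}

# dL/dA given dL/dAhat (both full matrices). Assumes no degree flooring was
# triggered. The diagonal of the returned matrix should be ignored by
# callers whose diagonal is structurally fixed (generated kernels).
normalize_adjacency_bwd <- function(dahat, a) {
  b <- a + diag(nrow(a))
  deg <- pmax(rowSums(b), 1e-8)
  s <- 1 / sqrt(deg)
  gb <- dahat * b
  tvec <- drop(gb %*% s)              # sum_j G_kj B_kj s_j  (s_k path, row k)
  uvec <- drop(crossprod(gb, s))      # sum_i G_ik B_ik s_i  (s_j path, row k)
  # the degree d_k is a row sum, so perturbing entry (k, l) only moves d_k:
  # both normalization corrections attach to the row index
  dahat * outer(s, s) -
    outer(0.5 * deg^(-1.5) * (tvec + uvec), rep(1, length(s)))
}

gcn_init <- function(n_roi, n_time, n_classes = 2L) {
  q <- n_time
  w_dims <- list(c(q, q %/% 2L), c(q %/% 2L, q %/% 4L), c(q %/% 4L, q %/% 8L))
  # signal-preserving init. Layer 1: truncated identity, so each feature is
  # one time sample of the diffused series. Deeper layers: nonnegative
  # pair-averaging (each output feature sums two disjoint inputs), so the
  # pooled per-ROI value aggregates the full sample budget when estimating
  # the diffused-signal magnitude — the class-informative statistic in this
  # architecture. Random-sign inits scramble that statistic before pooling;
  # identity-only inits read just q/8 of the samples. Small noise breaks
  # feature degeneracy for training.
  gconv <- vector("list", 3)
  gconv[[1]] <- matrix(rnorm(prod(w_dims[[1]]), sd = 0.01),
                       w_dims[[1]][1], w_dims[[1]][2])
  gconv[[1]][cbind(seq_len(w_dims[[1]][2]), seq_len(w_dims[[1]][2]))] <-
    gconv[[1]][cbind(seq_len(w_dims[[1]][2]), seq_len(w_dims[[1]][2]))] + sqrt(2)
  for (l in 2:3) {
    d <- w_dims[[l]]
    w <- matrix(rnorm(prod(d), sd = 0.01), d[1], d[2])
    for (k in seq_len(d[2])) {
      rows <- (2L * k - 1L):min(2L * k, d[1])
      w[rows, k] <- w[rows, k] + 1
    }
    gconv[[l]] <- w
  }
  # the perceptron follows the same philosophy: near-linear at init (each
  # hidden unit copies one pooled value, pairs aggregate, logits start at
  # zero), so early training behaves like logistic regression on the pooled
  # profile — the rule this architecture's class signal supports — rather
  # than sculpting an arbitrary function of 350 parameters from random
  # weights, which on small cohorts memorizes instead of generalizing
  l1 <- matrix(rnorm(n_roi * 32L, sd = 0.01), n_roi, 32L)
  l1[cbind(rep_len(seq_len(n_roi), 32L), 1:32)] <-
    l1[cbind(rep_len(seq_len(n_roi), 32L), 1:32)] + 1
  l2 <- matrix(rnorm(32L * 16L, sd = 0.01), 32L, 16L)
  for (k in 1:16) l2[(2L * k - 1L):(2L * k), k] <- l2[(2L * k - 1L):(2L * k), k] + 1
  l3 <- matrix(rnorm(16L * n_classes, sd = 0.01), 16L, n_classes)
  list(gconv = gconv,
       mlp = list(l1 = list(w = l1, b = rep(0, 32L)),
                  l2 = list(w = l2, b = rep(0, 16L)),
                  l3 = list(w = l3, b = rep(0, n_classes))))
}

#' Graph convolutional classification of a (network, series) pair
#'
#' Three graph convolutions `H <- relu(Ahat %*% H %*% W)` halving the feature
#' width each time (`q`, `q/2`, `q/4`, `q/8`, floored), a pooling layer that
#' averages each ROI's features to a single value, and a three-layer
#' perceptron (widths `n_roi`, 32, 16, classes) with softmax output. The same
#' classifier accepts empirical and generated pairs interchangeably.
#'
#' @param ahat normalized propagation operator (see [normalize_adjacency()]).
#' @param f node feature matrix, ROI time series (`n_roi` x `n_time`).
#' @param params classifier parameters.
#' @return list with `probs` (class probabilities summing to 1), `logits`,
#'   `pooled` (one value per ROI), and a backprop cache.
#' @export
gcn_forward <- function(ahat, f, params) {
  if (nrow(ahat) != nrow(f)) stop_shape("adjacency and features disagree on n_roi")
  if (nrow(params$gconv[[1]]) != ncol(f))
    stop_shape("feature width %d does not match classifier input %d",
               ncol(f), nrow(params$gconv[[1]]))
  hs <- list(f)
  zs <- list()
  h <- f
  for (l in 1:3) {
    z <- ahat %*% (h %*% params$gconv[[l]])
    h <- pmax(z, 0)
    zs[[l]] <- z
    hs[[l + 1]] <- h
  }
  pooled <- rowMeans(h)
  x <- matrix(pooled, 1)
  z1 <- linear_fwd(x, params$mlp$l1); a1 <- pmax(z1, 0)
  z2 <- linear_fwd(a1, params$mlp$l2); a2 <- pmax(z2, 0)
  logits <- linear_fwd(a2, params$mlp$l3)
  probs <- drop(softmax_rows(logits))
  list(probs = probs, logits = drop(logits), pooled = pooled,
       cache = list(ahat = ahat, hs = hs, zs = zs, x = x,
                    z1 = z1, a1 = a1, z2 = z2, a2 = a2))
}

# dlogits: gradient at the logits (for cross-entropy: probs - onehot).
# Returns parameter grads and dL/dAhat (needed when the adjacency is
# produced by the learnable kernel).
gcn_bwd <- function(dlogits, cache, params) {
  dlog <- matrix(dlogits, 1)
  g3 <- linear_bwd(dlog, cache$a2, params$mlp$l3)
  d2 <- g3$dx * (cache$z2 > 0)
  g2 <- linear_bwd(d2, cache$a1, params$mlp$l2)
  d1 <- g2$dx * (cache$z1 > 0)
  g1 <- linear_bwd(d1, cache$x, params$mlp$l1)
  dpooled <- drop(g1$dx)
  h3 <- cache$hs[[4]]
  dh <- matrix(dpooled / ncol(h3), nrow(h3), ncol(h3))
  dahat <- matrix(0, nrow(cache$ahat), ncol(cache$ahat))
  dgconv <- vector("list", 3)
  for (l in 3:1) {
    dz <- dh * (cache$zs[[l]] > 0)
    m <- cache$hs[[l]] %*% params$gconv[[l]]
    dahat <- dahat + tcrossprod(dz, m)
    dm <- crossprod(cache$ahat, dz)
    dgconv[[l]] <- crossprod(cache$hs[[l]], dm)
    dh <- dm %*% t(params$gconv[[l]])
  }
  list(grads = list(gconv = dgconv,
                    mlp = list(l1 = list(w = g1$dw, b = g1$db),
                               l2 = list(w = g2$dw, b = g2$db),
                               l3 = list(w = g3$dw, b = g3$db))),
       dahat = dahat)
}
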