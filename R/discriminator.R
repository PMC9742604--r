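#' Multi-channel temporal discriminator
#'
#' One independent fully connected network per ROI (no weight sharing), each
#' scoring that ROI's time series; the discriminator output is the arithmetic
#' mean of the per-channel scores. Hidden widths are `floor(q/2)`, `q`,
#' `floor(q/2)` with leaky-ReLU activations (slope 0.2); a final scalar layer
#' is linear (un-squashed), as the least-squares adversarial losses
#' presuppose real-valued scores.
#'
#' @name discriminator
#' @keywords internal
NULL

mtd_init <- function(n_roi, n_time) {
  q <- n_time
  h <- q %/% 2L
  lapply(seq_len(n_roi), function(i)
    list(l1 = linear_init(q, h), l2 = linear_init(h, q),
         l3 = linear_init(q, h), l4 = linear_init(h, 1, scale = sqrt(1 / h))))
}

#' Score a set of ROI time series as empirical or generated
#'
#' @param series `n_roi` x `n_time` matrix; channel `i` consumes row `i`.
#' @param params discriminator parameters (one network per ROI).
#' @return list with the scalar `score` (mean over channels), the per-channel
#'   scores `channel_scores`, and a cache for backpropagation.
#' @export
discriminate <- function(series, params) {
  n <- length(params)
  if (nrow(series) != n)
    stop_shape("series has %d rows but discriminator has %d channels",
               nrow(series), n)
  caches <- vector("list", n)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    p <- params[[i]]
    x0 <- series[i, , drop = FALSE]
    z1 <- linear_fwd(x0, p$l1); a1 <- leaky_relu(z1)
    z2 <- linear_fwd(a1, p$l2); a2 <- leaky_relu(z2)
    z3 <- linear_fwd(a2, p$l3); a3 <- leaky_relu(z3)
    z4 <- linear_fwd(a3, p$l4)
    vals[i] <- z4[1, 1]
    caches[[i]] <- list(x0 = x0, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                        z3 = z3, a3 = a3)
  }
  list(score = mean(vals), channel_scores = vals, caches = caches)
}

# dscore: dL/d(mean score). Returns parameter grads and dL/dseries.
mtd_bwd <- function(dscore, fwd, params, slope = 0.2) {
  n <- length(params)
  dseries <- matrix(0, n, ncol(fwd$caches[[1]]$x0))
  grads <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params[[i]]; ch <- fwd$caches[[i]]
    d4 <- matrix(dscore / n, 1, 1)
    g4 <- linear_bwd(d4, ch$a3, p$l4)
    d3 <- g4$dx * ifelse(ch$z3 > 0, 1, slope)
    g3 <- linear_bwd(d3, ch$a2, p$l3)
    d2 <- g3$dx * ifelse(ch$z2 > 0, 1, slope)
    g2 <- linear_bwd(d2, ch$a1, p$l2)
    d1 <- g2$dx * ifelse(ch$z1 > 0, 1, slope)
    g1 <- linear_bwd(d1, ch$x0, p$l1)
    dseries[i, ] <- g1$dx
    grads[[i]] <- list(l1 = list(w = g1$dw, b = g1$db),
                       l2 = list(w = g2$dw, b = g2$db),
                       l3 = list(w = g3$dw, b = g3$db),
                       l4 = list(w = g4$dw, b = g4$db))
  }
  list(grads = grads, dseries = dseries)
}
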