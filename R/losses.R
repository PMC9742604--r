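#' Training losses
#'
#' The five objectives of the adversarial pipeline: a reconstruction loss
#' tying generated to empirical series, least-squares adversarial losses for
#' generator and discriminator, a two-path cross-entropy classification loss,
#' and a Frobenius-norm regularizer on the kernel transform. The hybrid cost
#' is `L_all = L_rec + L_g + L_d + L_cls + lambda * L_reg`.
#'
#' @name losses
NULL

#' @describeIn losses reconstruction discrepancy between generated and
#'   empirical series. `norm = "mad"` (default) is the entrywise mean
#'   absolute deviation over all `n_roi * n_time` entries — the metric used
#'   to monitor convergence. `norm = "frobenius"` is the Frobenius norm of
#'   the difference, the form the training objective optimizes: its gradient
#'   grows with the residual, which keeps the reconstruction signal
#'   commensurate with the adversarial gradient in short runs.
#' @param fg,fe generated and empirical series matrices of equal shape.
#' @param norm `"mad"` or `"frobenius"`.
#' @export
loss_rec <- function(fg, fe, norm = c("mad", "frobenius")) {
  if (!all(dim(fg) == dim(fe))) stop_shape("series shapes disagree")
  switch(match.arg(norm),
         mad = mean(abs(fg - fe)),
         frobenius = sqrt(sum((fg - fe)^2)))
}

#' @describeIn losses least-squares generator loss `mean((1 - d_fake)^2)`;
#'   zero exactly when every fake score is 1.
#' @param d_fake,d_real discriminator scores on generated / empirical series.
#' @export
loss_g <- function(d_fake) mean((1 - d_fake)^2)

#' @describeIn losses least-squares discriminator loss
#'   `mean(d_fake^2) + mean((1 - d_real)^2)`; zero iff fakes score 0 and
#'   reals score 1.
#' @export
loss_d <- function(d_fake, d_real) mean(d_fake^2) + mean((1 - d_real)^2)

#' @describeIn losses two-path cross-entropy: the sum of the negative
#'   log-probability of the true class under the generated-path and
#'   empirical-path predictions, averaged over the batch. Probabilities are
#'   clipped to `[1e-12, 1]` before the log.
#' @param probs_generated,probs_empirical matrices (batch x classes) or
#'   vectors of class probabilities.
#' @param y one-hot label matrix (batch x classes) or vector.
#' @export
loss_cls <- function(probs_generated, probs_empirical, y) {
  pg <- rbind(probs_generated)
  pe <- rbind(probs_empirical)
  yy <- rbind(y)
  clip <- function(p) pmin(pmax(p, 1e-12), 1)
  mean(rowSums(-yy * log(clip(pg))) + rowSums(-yy * log(clip(pe))))
}

#' @describeIn losses Frobenius norm of the kernel transform matrix.
#' @param w the `n_time` x `n_time` kernel transform.
#' @export
loss_reg <- function(w) sqrt(sum(w^2))

loss_reg_grad <- function(w) {
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12) matrix(0, nrow(w), ncol(w)) else w / nrm
}
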