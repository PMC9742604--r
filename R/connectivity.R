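#' Learnable Gaussian-kernel connectivity from ROI time series
#'
#' Maps an `n_roi` x `n_time` series matrix to a connectivity matrix through
#' `A[i, j] = exp(-||(F[i, ] - F[j, ]) %*% W||^2 / (2 * sigma^2))`, where `W`
#' is a learnable `n_time` x `n_time` series transform and `sigma` the kernel
#' bandwidth controlling sparsity (default 2). Entries lie in (0, 1], the
#' diagonal is exactly 1, and symmetry is exact because each unordered pair
#' is evaluated once.
#'
#' @param series `n_roi` x `n_time` matrix of ROI time series.
#' @param w `n_time` x `n_time` transform matrix.
#' @param sigma kernel bandwidth, must be positive.
#' @return symmetric `n_roi` x `n_roi` matrix with unit diagonal.
#' @examples
#' f <- matrix(rnorm(40), 4, 10)
#' a <- gaussian_connectivity(f, diag(10))
#' stopifnot(isSymmetric(a), all(diag(a) == 1))
#' @export
gaussian_connectivity <- function(series, w, sigma = 2) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (ncol(series) != nrow(w) || nrow(w) != ncol(w))
    stop_shape("w must be n_time x n_time")
  m <- series %*% w
  n <- nrow(m)
  a <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    dif <- m[(i + 1):n, , drop = FALSE] -
      matrix(m[i, ], n - i, ncol(m), byrow = TRUE)
    val <- exp(-rowSums(dif^2) / (2 * sigma^2))
    a[i, (i + 1):n] <- val
    a[(i + 1):n, i] <- val
  }
  dimnames(a) <- list(rownames(series), rownames(series))
  a
}

# Gradients of a scalar loss through the kernel. `da` is dL/dA (both
# triangles populated; the diagonal is ignored since A[i,i] is constant).
# Returns dL/dW and dL/dseries.
gaussian_connectivity_bwd <- function(da, series, w, sigma, a) {
  m <- series %*% w
  g <- -(da * a) / (2 * sigma^2)    # dL/d(squared distance), per ordered entry
  g <- g + t(g)                     # fold the two ordered entries of a pair
  diag(g) <- 0
  # d(sq dist ij)/dM_i = 2 (M_i - M_j)
  dm <- 2 * (m * rowSums(g) - g %*% m)
  dw <- crossprod(series, dm)
  dseries <- dm %*% t(w)
  list(dw = dw, dseries = dseries)
}
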