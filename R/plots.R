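#' Plot a connectivity matrix
#'
#' Simple base-graphics heat map with ROI 1 in the top-left corner.
#'
#' @param a square connectivity (or difference) matrix.
#' @param main plot title.
#' @param zlim color range; defaults to the symmetric data range.
#' @export
plot_connectivity <- function(a, main = "", zlim = NULL) {
  n <- nrow(a)
  if (is.null(zlim)) {
    r <- max(abs(range(a)))
    zlim <- c(-r, r)
  }
  graphics::image(seq_len(n), seq_len(n), t(a[n:1, , drop = FALSE]),
                  zlim = zlim, xlab = "ROI", ylab = "ROI", main = main,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  useRaster = TRUE)
  invisible(NULL)
}

#' @export
plot.fbn_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::matplot(h$step, cbind(h$l_rec, h$l_g, h$l_d, h$l_cls),
                    type = "l", lty = 1, xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", c("rec", "gen", "disc", "cls"),
                   col = 1:4, lty = 1, bty = "n", cex = 0.8)
  graphics::plot(seq_along(x$epoch_mae), x$epoch_mae, type = "b",
                 xlab = "epoch", ylab = "MAE (generated vs empirical)")
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
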